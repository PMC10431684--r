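# Expected values below were computed with brute-force scans of the toy
# incidence Y = {(g1,m1),(g1,m2),(g2,m2),(g3,m3)} and frozen.

test_that("derivation operators match brute-force scans of Y", {
  ctx <- toy_context()
  expect_equal(derive_objects(integer(), ctx), 1:3)   # empty set: all objects
  expect_equal(derive_objects(2, ctx), c(1L, 2L))     # {m2} -> {g1, g2}
  expect_equal(derive_attrs(integer(), ctx), 1:3)
  expect_equal(derive_attrs(c(1, 2), ctx), 2L)        # {g1, g2} -> {m2}
  expect_equal(derive_attrs(3, ctx), 3L)              # {g3} -> {m3}
  expect_error(derive_objects(9, ctx), "unknown attribute")
  expect_error(derive_attrs(0, ctx), "unknown object")

  full <- formal_context(c("g1", "g2"), c("m1", "m2"), matrix(TRUE, 2, 2))
  expect_equal(derive_objects(1, full), c(1L, 2L))
})

test_that("closure_of returns closed concepts and is idempotent", {
  ctx <- toy_context()
  top <- closure_of(integer(), ctx)
  expect_equal(top$extent, 1:3)
  expect_equal(top$intent, integer())   # no attribute shared by all three

  c1 <- closure_of(1, ctx)              # {m1} closes to ({g1}, {m1,m2})
  expect_equal(c1$extent, 1L)
  expect_equal(c1$intent, c(1L, 2L))

  for (attrs in list(integer(), 1, 2, c(1, 3), 1:3)) {
    cpt <- closure_of(attrs, ctx)
    expect_equal(derive_objects(cpt$intent, ctx), cpt$extent)
    expect_equal(derive_attrs(cpt$extent, ctx), cpt$intent)
    expect_true(all(attrs %in% cpt$intent))
    again <- closure_of(cpt$intent, ctx)
    expect_equal(again$extent, cpt$extent)
    expect_equal(again$intent, cpt$intent)
  }
})

test_that("augment grows the intent, shrinks the extent, and closes", {
  ctx <- toy_context()
  top <- closure_of(integer(), ctx)
  a <- augment(top, 2, ctx)             # add m2
  expect_equal(a$extent, c(1L, 2L))
  expect_equal(a$intent, 2L)

  # closure may add more than the augmented attribute
  c1 <- concept(1L, c(1L, 2L))
  b <- augment(c1, 3, ctx)
  expect_equal(b$extent, integer())
  expect_equal(b$intent, 1:3)

  expect_error(augment(c1, 1, ctx), "already in intent")
})

test_that("is_canonical implements the min/max predecessor condition", {
  expect_true(is_canonical(c(1, 2), c(1, 2, 4)))    # min diff 4 > max 2
  expect_false(is_canonical(c(1, 3), c(1, 2, 3)))   # min diff 2 < max 3
  expect_true(is_canonical(integer(), 1))           # empty parent convention
  expect_error(is_canonical(c(1, 2), c(1, 2)), "strictly contain")
})

test_that("enumerate_concepts visits known lattices exactly", {
  empty2 <- formal_context(c("g1", "g2"), c("m1", "m2"), matrix(FALSE, 2, 2))
  expect_equal(enumerate_concepts(empty2), 2)   # (G, {}) and ({}, M)

  full2 <- formal_context(c("g1", "g2"), c("m1", "m2"), matrix(TRUE, 2, 2))
  expect_equal(enumerate_concepts(full2), 1)

  got <- list()
  n <- enumerate_concepts(identity_context(3), visitor = function(cpt, d) {
    got[[length(got) + 1L]] <<- cpt
  })
  expect_equal(n, 5)
  expect_equal(length(got), 5)
  expect_setequal(
    concept_strings(got),
    concept_strings(list(concept(1:3, integer()), concept(1, 1),
                         concept(2, 2), concept(3, 3),
                         concept(integer(), 1:3))))
})

test_that("enumeration equals brute force with zero duplicates on random contexts", {
  withr::local_seed(101)
  for (rep in 1:40) {
    ctx <- random_context(sample(2:9, 1), sample(2:9, 1),
                          sample(c(0.1, 0.3, 0.5, 0.9), 1))
    got <- list()
    cnt <- enumerate_concepts(ctx, visitor = function(cpt, d) {
      got[[length(got) + 1L]] <<- cpt
    })
    keys <- concept_strings(got)
    expect_equal(anyDuplicated(keys), 0)
    expect_equal(cnt, length(got))
    expect_equal(keys, concept_strings(enumerate_concepts_bruteforce(ctx)))
    # closure invariant on every visited concept
    for (cpt in got) {
      expect_equal(derive_objects(cpt$intent, ctx), cpt$extent)
      expect_equal(derive_attrs(cpt$extent, ctx), cpt$intent)
    }
  }
})

test_that("DFS paths are lattice chains and min_extent pruning is sound", {
  withr::local_seed(7)
  for (rep in 1:10) {
    ctx <- random_context(6, 6, 0.4)
    for (chain in dfs_chains(ctx)) {
      if (length(chain) < 2) next
      for (t in 2:length(chain)) {
        expect_true(all(chain[[t]]$extent %in% chain[[t - 1]]$extent))
        expect_true(all(chain[[t - 1]]$intent %in% chain[[t]]$intent))
      }
    }
    # pruned enumeration = unpruned concepts with extent >= threshold
    alpha <- 2L
    big <- Filter(function(c) length(c$extent) >= alpha,
                  enumerate_concepts_bruteforce(ctx))
    kept <- list()
    enumerate_concepts(ctx, min_extent = alpha, visitor = function(cpt, d) {
      kept[[length(kept) + 1L]] <<- cpt
    })
    expect_equal(concept_strings(kept), concept_strings(big))
  }
})

test_that("brute-force oracle refuses oversized contexts", {
  wide <- formal_context("g1", paste0("m", 1:16), matrix(TRUE, 1, 16))
  expect_error(enumerate_concepts_bruteforce(wide), "too large")
})
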