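test_that("overlap_rates follows the min/max size formula", {
  c1 <- concept(1:4, 1:2)
  c2 <- concept(1:2, 1:3)
  expect_equal(overlap_rates(c1, c2),
               c(sigma1 = 0.5, sigma2 = 2 / 3))
  expect_equal(overlap_rates(c2, c1), overlap_rates(c1, c2))   # symmetric
  expect_equal(overlap_rates(c1, c1), c(sigma1 = 1, sigma2 = 1))

  # ({g1},{m1}) vs (G, {}) in the 3x3 identity lattice
  expect_equal(overlap_rates(concept(1, 1), concept(1:3, integer())),
               c(sigma1 = 1 / 3, sigma2 = 0))
  expect_error(overlap_rates(concept(1:2, 1), concept(2:3, 1)),
               "not comparable")
})

test_that("is_nontrivial applies both thresholds with >=", {
  rec <- overlap_record(concept(1:4, 1:2), concept(1:2, 1:3))
  expect_true(is_nontrivial(rec, nss_params(alpha = 2, rho = 0.5)))
  expect_false(is_nontrivial(rec, nss_params(alpha = 3, rho = 0.5)))
  expect_false(is_nontrivial(rec, nss_params(alpha = 2, rho = 0.7)))
  # distinct comparable concepts can never pass rho = 1
  expect_false(is_nontrivial(rec, nss_params(alpha = 1, rho = 1)))
})

test_that("structure_hole is the exclusive-region product and dominates inner holes", {
  lower <- concept(1:3, 1)
  upper <- concept(1:2, 1:2)
  h <- structure_hole(lower, upper)
  expect_equal(nrow(h), 1)
  expect_equal(unlist(h), c(object = 3L, attribute = 2L))
  expect_equal(nrow(structure_hole(lower, lower)), 0)
  expect_error(structure_hole(upper, lower), "not ordered")

  # the extreme pair's hole contains every inner pair's hole; an equality
  # does not hold in general (the containment can be strict)
  withr::local_seed(5)
  strict_seen <- FALSE
  for (rep in 1:10) {
    ctx <- random_context(6, 6, 0.4)
    for (chain in dfs_chains(ctx)) {
      if (length(chain) < 3) next
      for (t in seq_len(length(chain) - 2)) {
        c1 <- chain[[t]]; c2 <- chain[[t + 1]]; c3 <- chain[[t + 2]]
        h13 <- paste(structure_hole(c1, c3)$object,
                     structure_hole(c1, c3)$attribute)
        inner <- union(paste(structure_hole(c1, c2)$object,
                             structure_hole(c1, c2)$attribute),
                       paste(structure_hole(c2, c3)$object,
                             structure_hole(c2, c3)$attribute))
        expect_length(setdiff(inner, h13), 0)
        if (length(setdiff(h13, inner))) strict_seen <- TRUE
      }
    }
  }
  expect_true(strict_seen)
})

test_that("sigma rates are multiplicative and sizes monotone along chains", {
  withr::local_seed(6)
  for (rep in 1:10) {
    ctx <- random_context(7, 7, 0.35)
    for (chain in dfs_chains(ctx)) {
      if (length(chain) < 2) next
      exts <- vapply(chain, function(c) length(c$extent), 0L)
      ints <- vapply(chain, function(c) length(c$intent), 0L)
      expect_true(all(diff(exts) <= 0))   # extents shrink downward
      expect_true(all(diff(ints) >= 1))   # intents strictly grow
      if (length(chain) < 3) next
      for (t in seq_len(length(chain) - 2)) {
        s13 <- overlap_rates(chain[[t]], chain[[t + 2]])
        s12 <- overlap_rates(chain[[t]], chain[[t + 1]])
        s23 <- overlap_rates(chain[[t + 1]], chain[[t + 2]])
        expect_equal(s13[["sigma1"]], s12[["sigma1"]] * s23[["sigma1"]],
                     tolerance = 1e-12)
        expect_equal(s13[["sigma2"]], s12[["sigma2"]] * s23[["sigma2"]],
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("collect_marked_pairs matches the all-pairs oracle on the planted two-block context", {
  net <- two_block_network()
  ctx <- to_context(net)
  params <- nss_params(alpha = 2, rho = 0.4)
  marked <- collect_marked_pairs(ctx, params)
  oracle <- marked_oracle(ctx, params)
  expect_equal(pair_strings(marked), pair_strings(oracle))
  expect_equal(nrow(marked), 8)   # the two 2x2 exclusive-region products
  # never a present edge
  expect_length(intersect(pair_strings(marked), pair_strings(net$present)), 0)
})

test_that("degenerate cases mark nothing", {
  full <- formal_context(c("g1", "g2"), c("m1", "m2"), matrix(TRUE, 2, 2))
  expect_equal(nrow(collect_marked_pairs(full, nss_params(alpha = 1, rho = 0))), 0)
  ctx <- to_context(two_block_network())
  expect_equal(nrow(collect_marked_pairs(ctx, nss_params(alpha = 2, rho = 1))), 0)
})

test_that("marked pairs are stable under node relabeling on planted fixtures", {
  withr::local_seed(31)
  net <- two_block_network()
  params <- nss_params(alpha = 2, rho = 0.4)
  base <- pair_strings(collect_marked_pairs(to_context(net), params))
  for (rep in 1:5) {
    net2 <- bipartite_network(sample(net$left), sample(net$right), net$present)
    expect_equal(pair_strings(collect_marked_pairs(to_context(net2), params)),
                 base)
  }
})

test_that("select_negatives draws floor(rate * pool), disjoint and seeded", {
  # 3x3 network, 3 present edges, 1 marked pair -> pool of 5
  net <- net_from_matrix(rbind(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1)))
  marked <- data.frame(left = "a3", right = "b1")
  params <- nss_params(alpha = 1, rho = 0, sample_rate = 0.5, seed = 4)
  negs <- select_negatives(net, marked, params)
  expect_equal(nrow(negs), 2)   # floor(0.5 * 5)
  expect_length(intersect(pair_strings(negs), pair_strings(net$present)), 0)
  expect_length(intersect(pair_strings(negs), pair_strings(marked)), 0)

  params$sample_rate <- 1
  expect_equal(nrow(select_negatives(net, marked, params)), 5)
  params$sample_rate <- 0
  expect_equal(nrow(select_negatives(net, marked, params)), 0)

  params$sample_rate <- 0.5
  expect_identical(select_negatives(net, marked, params),
                   select_negatives(net, marked, params))
  params$sample_rate <- 2
  expect_error(select_negatives(net, marked, params), "sample_rate")
})

test_that("select_negatives_random equals marked-free selection", {
  net <- net_from_matrix(rbind(c(1, 0), c(0, 0)))
  params <- nss_params(alpha = 1, rho = 0, sample_rate = 1, seed = 2)
  expect_equal(nrow(select_negatives_random(net, params)), 3)
  expect_identical(select_negatives_random(net, params),
                   select_negatives(net, data.frame(left = character(),
                                                    right = character()),
                                    params))
})
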