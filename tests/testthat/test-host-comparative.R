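test_that("pair enumeration routes similar and dissimilar host pairs correctly", {
  sets <- list(a1 = c("u", "x"), a2 = c("u", "y"),
               b1 = c("u", "x"), b2 = c("u", "y"))
  meta <- make_meta(c("a1", "a2", "b1", "b2"),
                    c("FA", "FA", "FB", "FB"),
                    host_type = c("vertebrate", "insect",
                                  "vertebrate", "insect"))
  sh <- compute_sharing(sets_to_counts(sets))
  cmp <- cross_family_pair_sharing(sh, meta, "FA", "FB", "vertebrate")
  expect_equal(cmp$n_similar, 1)
  expect_equal(cmp$similar$a, "a1"); expect_equal(cmp$similar$b, "b1")
  expect_equal(cmp$n_dissimilar, 2)
  expect_setequal(paste(cmp$dissimilar$a, cmp$dissimilar$b),
                  c("a1 b2", "a2 b1"))
  # the insect-insect pair is excluded entirely
  expect_false(any(paste(rbind(cmp$similar, cmp$dissimilar)$a,
                         rbind(cmp$similar, cmp$dissimilar)$b) == "a2 b2"))

  # all similar hosts -> untestable, not an error
  meta_all <- make_meta(c("a1", "a2", "b1", "b2"),
                        c("FA", "FA", "FB", "FB"),
                        host_type = "vertebrate")
  cmp_all <- cross_family_pair_sharing(sh, meta_all, "FA", "FB",
                                       "vertebrate")
  expect_true(cmp_all$untestable)
  expect_equal(cmp_all$n_dissimilar, 0)

  expect_error(cross_family_pair_sharing(sh, meta, "FZ", "FB",
                                         "vertebrate"), "no viruses")
})

test_that("exact one-sided MWW matches closed-form enumeration", {
  r <- mww_one_sided(c(3, 4), c(1, 2))
  expect_equal(r$method, "exact")
  expect_equal(r$U, 4)
  expect_equal(r$p_value, 1 / 6, tolerance = 1e-12)

  expect_equal(mww_one_sided(1, 2)$p_value, 1)
  expect_equal(mww_one_sided(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(mww_one_sided(numeric(), 1), "nonempty")
})

test_that("exact MWW agrees with wilcox.test when ties are absent", {
  set.seed(21)
  for (rep in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2)
    got <- mww_one_sided(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample branch matches the tie-corrected normal approximation", {
  set.seed(22)
  x <- round(stats::rnorm(25), 1); y <- round(stats::rnorm(25, -0.3), 1)
  got <- mww_one_sided(x, y)              # 625 products > 400
  expect_equal(got$method, "normal")
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                       correct = TRUE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)

  # exact and approximate branches agree closely near the switch point
  x2 <- stats::rnorm(15); y2 <- stats::rnorm(15)
  ex <- mww_one_sided(x2, y2, exact_limit = 400)   # 225 <= 400: exact
  ap <- mww_one_sided(x2, y2, exact_limit = 1)     # forced approximation
  expect_equal(ex$method, "exact"); expect_equal(ap$method, "normal")
  expect_lt(abs(ex$p_value - ap$p_value), 0.02)
})

test_that("host-shared screen reproduces the hand-evaluated set logic", {
  counts <- sets_to_counts(list(a1 = c("g1", "g2"), a2 = "g2",
                                b1 = c("g1", "g3"), b2 = "g3"))
  meta <- make_meta(c("a1", "a2", "b1", "b2"),
                    c("FA", "FA", "FB", "FB"),
                    host_type = c("vertebrate", "insect",
                                  "vertebrate", "insect"))
  rep <- host_shared_orthogroups(counts, meta, "FA", "FB",
                                 "vertebrate", "insect")
  expect_equal(rep$orthogroup_id, "g1")
  expect_equal(rep$freq_target, 1)
  expect_equal(rep$freq_reference, 0)
  expect_equal(rep$freq_diff, 1)
  # g2 is in FA viruses only and g3 in FB only: neither is shared between
  # the families in either direction, so the swapped report is empty
  swapped <- host_shared_orthogroups(counts, meta, "FA", "FB",
                                     "insect", "vertebrate")
  expect_equal(nrow(swapped), 0)
  # the two directions can never share an orthogroup
  expect_length(intersect(rep$orthogroup_id, swapped$orthogroup_id), 0)

  meta_gap <- make_meta(c("a1", "a2", "b1", "b2"),
                        c("FA", "FA", "FB", "FB"),
                        host_type = c("vertebrate", "vertebrate",
                                      "vertebrate", "insect"))
  expect_error(host_shared_orthogroups(counts, meta_gap, "FA", "FB",
                                       "vertebrate", "insect"),
               "no insect-host virus in family FA")
})

test_that("screen equals the double-loop oracle on random fixtures", {
  set.seed(33)
  for (rep in 1:25) {
    fx <- random_host_fixture(n_per_stratum = sample(1:3, 1),
                              pool = sample(8:20, 1))
    if (ncol(fx$counts) == 0) next
    got <- host_shared_orthogroups(fx$counts, fx$meta, "FA", "FB",
                                   "vertebrate", "insect")
    want <- oracle_host_screen(fx$counts, fx$meta, "FA", "FB",
                               "vertebrate", "insect")
    expect_equal(got$orthogroup_id, want$orthogroup_id)
    expect_equal(got$freq_target, want$freq_target, tolerance = 1e-12)
    expect_equal(got$freq_reference, want$freq_reference, tolerance = 1e-12)
    expect_equal(got$mean_copy_number, want$mean_copy_number,
                 tolerance = 1e-12)
    # swapped direction is always disjoint
    rev <- host_shared_orthogroups(fx$counts, fx$meta, "FA", "FB",
                                   "insect", "vertebrate")
    expect_length(intersect(got$orthogroup_id, rev$orthogroup_id), 0)
  }
})

test_that("host_compare wires pair enumeration into the rank test", {
  sim <- simulate_dataset(simulation_params(
    n_families = 2, lineages_per_family = 2, genomes_per_lineage = 3,
    seed = 2))
  sh <- compute_sharing(build_count_matrix(sim$catalog, sim$meta))
  cmp <- host_compare(sh, sim$meta, "Fam1", "Fam2", "vertebrate")
  expect_s3_class(cmp, "host_pair_comparison")
  expect_false(cmp$untestable)
  # planted host pools: similar-host pairs share more
  expect_lt(cmp$p_value, 0.05)
  expect_gt(mean(cmp$similar$S), mean(cmp$dissimilar$S))
})
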