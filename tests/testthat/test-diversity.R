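test_that("lineage averaging matches direct group means", {
  lm <- lineage_means(c(g1 = 100, g2 = 200), c(g1 = "L1", g2 = "L1"))
  expect_equal(unname(lm["L1"]), 150)
  lm <- lineage_means(c(g1 = 37), c(g1 = "L1"))
  expect_equal(unname(lm["L1"]), 37)

  set.seed(3)
  vals <- stats::setNames(stats::rnorm(20), sprintf("g%02d", 1:20))
  lmap <- stats::setNames(sample(c("La", "Lb", "Lc"), 20, TRUE),
                          names(vals))
  got <- lineage_means(vals, lmap)
  for (l in unique(lmap))    # independent loop-and-average oracle
    expect_equal(unname(got[l]), mean(vals[names(lmap)[lmap == l]]))

  expect_error(lineage_means(c(gX = 1), c(gY = "L1")), "without a lineage")
})

test_that("family SD uses the sample convention and marks single-lineage families missing", {
  fm <- c(L1 = "F", L2 = "F")
  expect_equal(unname(family_sd(c(L1 = 150, L2 = 50), fm)["F"]),
               sqrt(5000))
  expect_equal(unname(family_sd(c(L1 = 5, L2 = 5), fm)["F"]), 0)
  expect_true(is.na(family_sd(c(L1 = 7), c(L1 = "F"))["F"]))

  # translation invariance and linear scaling
  set.seed(9)
  v <- stats::setNames(stats::rnorm(6), sprintf("L%d", 1:6))
  fm6 <- stats::setNames(rep(c("F1", "F2"), each = 3), names(v))
  base <- family_sd(v, fm6)
  expect_equal(family_sd(v + 100, fm6), base)
  expect_equal(family_sd(3 * v, fm6), 3 * base)
})

test_that("between-lineage patristic distance averages cross-lineage tip pairs", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  lmap <- c(A = "L1", B = "L1", C = "L2")
  fmap <- c(L1 = "F", L2 = "F")
  got <- mean_interlineage_patristic(tr, lmap, fmap)
  expect_equal(unname(got["F"]), mean(c(5, 6)))  # d(A,C), d(B,C)

  # two single-tip lineages reduce to the plain tip distance
  got <- mean_interlineage_patristic(tr, c(A = "L1", C = "L2"), fmap)
  expect_equal(unname(got["F"]), 5)

  # single-lineage family is undefined
  got <- mean_interlineage_patristic(tr, c(A = "L1", B = "L1"),
                                     c(L1 = "F"))
  expect_true(is.na(got["F"]))

  expect_error(mean_interlineage_patristic(tr, c(Z = "L1", C = "L2"), fmap),
               "missing from tree")

  # with one genome per lineage, equals the plain mean pairwise distance
  tr2 <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1,D:1):2);")
  lmap2 <- c(A = "l1", B = "l2", C = "l3", D = "l4")
  fmap2 <- stats::setNames(rep("F", 4), paste0("l", 1:4))
  D <- ape::cophenetic.phylo(tr2)
  expect_equal(unname(mean_interlineage_patristic(tr2, lmap2, fmap2)["F"]),
               mean(D[upper.tri(D)]))
})

test_that("Shannon host diversity spans 0 to ln 6 and matches direct evaluation", {
  fm <- stats::setNames(rep("F", 6), sprintf("L%d", 1:6))
  uniform_one <- stats::setNames(rep("Opisthokonta", 6), names(fm))
  expect_equal(unname(shannon_host_diversity(uniform_one, fm)["F"]), 0)

  six_way <- stats::setNames(c("Amoebozoa", "Archaeplastida", "Discoba",
                               "Haptista", "Opisthokonta", "SAR"),
                             names(fm))
  expect_equal(unname(shannon_host_diversity(six_way, fm)["F"]), log(6),
               tolerance = 1e-12)

  fm3 <- stats::setNames(rep("F", 3), c("L1", "L2", "L3"))
  split21 <- stats::setNames(c("SAR", "SAR", "Haptista"), names(fm3))
  expect_equal(unname(shannon_host_diversity(split21, fm3)["F"]),
               -(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3),
               tolerance = 1e-12)

  # permutation invariance in lineage order, bounds on random draws
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(2:8, 1)
    sgs <- sample(c("Amoebozoa", "Archaeplastida", "Discoba", "Haptista",
                    "Opisthokonta", "SAR"), k, TRUE)
    fmk <- stats::setNames(rep("F", k), sprintf("L%d", 1:k))
    lin_sg <- stats::setNames(sgs, names(fmk))
    d <- unname(shannon_host_diversity(lin_sg, fmk)["F"])
    expect_gte(d, 0); expect_lte(d, log(6) + 1e-12)
    perm <- sample(k)
    expect_equal(unname(shannon_host_diversity(lin_sg[perm], fmk)["F"]), d)
  }

  # unknown supergroups are excluded with a warning
  fm2 <- stats::setNames(rep("F", 2), c("L1", "L2"))
  expect_warning(
    d <- shannon_host_diversity(
      stats::setNames(c("SAR", "unknown"), names(fm2)), fm2),
    "unknown")
  expect_equal(unname(d["F"]), 0)
})

test_that("lineage supergroup assignment takes the majority and rejects ties", {
  meta <- make_meta(c("a", "b", "c"), "F", lineage = c("L1", "L1", "L1"),
                    host_supergroup = c("SAR", "SAR", "Haptista"))
  expect_equal(unname(lineage_supergroups(meta)["L1"]), "SAR")
  meta2 <- make_meta(c("a", "b"), "F", lineage = c("L1", "L1"),
                     host_supergroup = c("SAR", "Haptista"))
  expect_error(lineage_supergroups(meta2), "tied")
})

test_that("family variation report assembles all measures and honours missing inputs", {
  sim <- simulate_dataset(simulation_params(
    n_families = 2, lineages_per_family = 2, genomes_per_lineage = 2,
    seed = 5))
  rep_full <- family_variation_report(sim$meta, sim$catalog, sim$tree)
  expect_setequal(rep_full$family, c("Fam1", "Fam2"))
  expect_true(all(rep_full$lineage_count == 2))
  expect_true(all(rep_full$sd_protein_counts >= 0))
  expect_true(all(rep_full$host_diversity_D >= 0 &
                    rep_full$host_diversity_D <= log(6)))

  # no tree: patristic column missing, everything else present
  rep_nt <- family_variation_report(sim$meta, sim$catalog)
  expect_true(all(is.na(rep_nt$mean_patristic)))
  expect_equal(rep_nt$sd_protein_counts, rep_full$sd_protein_counts)

  # no protein index behind the catalog: singleton SD missing, never zero
  cat_noidx <- new_orthogroup_catalog(sim$catalog$members)
  rep_ns <- family_variation_report(sim$meta, cat_noidx, sim$tree)
  expect_true(all(is.na(rep_ns$sd_singleton_counts)))
})
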