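# Hand-built classified pair table over four sites (A-D): the combinatorics
# and counting oracle cases are exact.
fake_pairs <- function(labels, sites = c("A", "B", "C", "D"),
                       status = NULL) {
  sp <- t(combn(sites, 2))
  stopifnot(nrow(sp) == length(labels))
  if (is.null(status)) status <- rep("ok", length(labels))
  data.frame(pair_id = seq_len(nrow(sp)), site_a = sp[, 1], site_b = sp[, 2],
             ses = 0, rc = 0, process = labels, status = status,
             stringsAsFactors = FALSE)
}

test_that("pair counting matches the four-site worked example", {
  sites <- c("A", "B", "C", "D")
  expect_identical(nrow(site_pairs(sites)), 6L)
  one <- pairs_involving(dsu_target("A", "A"), sites)
  expect_identical(paste0(one$site_a, one$site_b), c("AB", "AC", "AD"))
  grp <- pairs_involving(dsu_target("AB", c("A", "B")), sites)
  expect_identical(paste0(grp$site_a, grp$site_b),
                   c("AB", "AC", "AD", "BC", "BD"))
  all_of_them <- pairs_involving(dsu_target("all", sites), sites)
  expect_identical(nrow(all_of_them), 6L)
  expect_error(pairs_involving(dsu_target("X", "X"), sites), "not present")
})

test_that("involved-pair counts follow the closed form C(n,2) - C(n-g,2)", {
  for (n in c(4, 7, 10)) {
    sites <- paste0("S", seq_len(n))
    for (g in c(1, 2, 3, n)) {
      got <- nrow(pairs_involving(dsu_target("g", sites[seq_len(g)]), sites))
      expect_equal(got, choose(n, 2) - choose(n - g, 2))
    }
  }
})

test_that("between-only counting drops within-group pairs", {
  sites <- c("A", "B", "C", "D")
  grp <- pairs_involving(dsu_target("AB", c("A", "B")), sites,
                         between_only = TRUE)
  expect_identical(paste0(grp$site_a, grp$site_b), c("AC", "AD", "BC", "BD"))
})

test_that("per-site fractions count involved pairs exactly", {
  pr <- fake_pairs(c("heterogeneous_selection",  # AB
                     "heterogeneous_selection",  # AC
                     "drift",                    # AD
                     "drift", "drift", "drift")) # BC BD CD
  res <- attribute_sites(pr, dsu_target("A", "A"))
  expect_identical(res$n_involved, 3L)
  expect_equal(res$heterogeneous_selection, 2 / 3)
  expect_equal(res$drift, 1 / 3)
  expect_equal(res$significant_fraction, 2 / 3)
  # the paper-style headline: all-drift involved pairs give significance 0
  res2 <- attribute_sites(fake_pairs(rep("drift", 6)),
                          dsu_target("AB", c("A", "B")))
  expect_identical(res2$n_involved, 5L)
  expect_equal(res2$significant_fraction, 0)
  expect_equal(res2$stochasticity, 1)
})

test_that("fractions sum to 1 and degenerate pairs leave the denominator", {
  pr <- fake_pairs(c("heterogeneous_selection", "dispersal_limitation",
                     NA, "drift", "homogenizing_dispersal", "drift"),
                   status = c("ok", "ok", "degenerate", "ok", "ok", "ok"))
  res <- attribute_sites(pr, list(dsu_target("A", "A"), dsu_target("C", "C")))
  procs <- assembly_processes()
  expect_equal(unname(rowSums(res[, procs])), c(1, 1))
  # pair AD (third in order) is degenerate: it involves A but not C
  expect_identical(res$n_involved, c(3L, 3L))
  expect_identical(res$n_evaluable, c(2L, 3L))
})

test_that("group summaries reproduce hand counting on a five-site toy", {
  sites <- paste0("S", 1:5)
  labels <- c("heterogeneous_selection",  # S1S2
              "heterogeneous_selection",  # S1S3
              "drift",                    # S1S4
              "dispersal_limitation",     # S1S5
              "drift",                    # S2S3
              "drift",                    # S2S4
              "homogeneous_selection",    # S2S5
              "drift",                    # S3S4
              "drift",                    # S3S5
              "drift")                    # S4S5
  pr <- fake_pairs(labels, sites = sites)
  md <- data.frame(band = c("low", "low", "high", "high", "high"),
                   row.names = sites)
  res <- group_summary(pr, md, "band")
  low <- res[res$target_id == "low", ]
  # low = {S1,S2}: pairs 12,13,14,15,23,24,25 -> 7 involved
  expect_identical(low$n_involved, 7L)
  expect_equal(low$heterogeneous_selection, 2 / 7)
  expect_equal(low$homogeneous_selection, 1 / 7)
  expect_equal(low$dispersal_limitation, 1 / 7)
  expect_equal(low$drift, 3 / 7)
  expect_equal(low$stochasticity, 4 / 7)
  high <- res[res$target_id == "high", ]
  # high = {S3,S4,S5}: all pairs except S1S2 -> 9 involved, 7 drift-ish
  expect_identical(high$n_involved, 9L)
  expect_equal(high$significant_fraction, 3 / 9)
  expect_error(group_summary(pr, md[1:4, , drop = FALSE], "band"),
               "without metadata")
})

test_that("stochasticity hits its logical extremes", {
  all_het <- fake_pairs(rep("heterogeneous_selection", 6))
  expect_equal(attribute_sites(all_het, dsu_target("A", "A"))$stochasticity, 0)
  all_drift <- fake_pairs(rep("drift", 6))
  expect_equal(attribute_sites(all_drift, dsu_target("A", "A"))$stochasticity, 1)
})
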