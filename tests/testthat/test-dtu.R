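test_that("decision rules reproduce the five-way attribution and boundaries", {
  # rule 1: significance lost after removal
  expect_identical(decision_rules(2.6, 1.1)$process, "heterogeneous_selection")
  # still significant after removal: rule 5
  expect_identical(decision_rules(2.6, 2.7)$process, "drift")
  # rule 2 and its strict boundary (-2.1 is not > -2)
  expect_identical(decision_rules(-2.4, -1.0)$process, "homogeneous_selection")
  expect_identical(decision_rules(-2.4, -2.1)$process, "drift")
  # rules 3/4 under the consistent labeling
  expect_identical(decision_rules(0.2, 0.3, 0.97, 0.40)$process,
                   "dispersal_limitation")
  expect_identical(decision_rules(0.2, 0.3, -0.97, -0.40)$process,
                   "homogenizing_dispersal")
  # paper-literal labeling swaps the two dispersal labels
  expect_identical(
    decision_rules(0.2, 0.3, 0.97, 0.40, rule_labels = "paper-literal")$process,
    "homogenizing_dispersal")
  expect_identical(
    decision_rules(0.2, 0.3, -0.97, -0.40, rule_labels = "paper-literal")$process,
    "dispersal_limitation")
  # removal leaving RC significant: rule 5
  expect_identical(decision_rules(0.2, 0.3, 0.97, 0.96)$process, "drift")
  # masking diagnostic: nonsignificant turning significant
  dr <- decision_rules(1.0, 2.5)
  expect_identical(dr$process, "drift")
  expect_true(dr$masking)
  expect_error(decision_rules(0.2, 0.3, NA, NA), "rc required")
})

test_that("removing a taxon from a 3-taxon toy leaves the remaining distance", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- cophenetic_matrix(tr)
  # sites {A,B} vs {A,C}; removing A leaves singletons B vs C
  m <- matrix(c(2, 2, 0,
                3, 0, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  cfg <- null_config(seed = 1, n_reps = 10)
  rr <- remove_and_recompute(m, tr, removal_target("A", "A"), cfg)
  expect_equal(rr$beta_mntd_i, D["B", "C"])
})

test_that("removal metrics equal a from-scratch run on the pre-filtered table", {
  sim <- simulate_assembly("heterogeneous_selection", seed = 19, n_taxa = 20,
                           n_sites = 5, site_total = 300)
  al <- align_community_tree(sim$community, sim$tree)
  cfg <- null_config(seed = 23, n_reps = 100)
  target <- removal_target("grp", colnames(al$community)[c(2, 7, 11)])
  rr <- remove_and_recompute(al$community, al$tree, target, cfg)
  reduced <- al$community[, setdiff(colnames(al$community), target$taxa)]
  scratch <- classify_communities(as_community_matrix(reduced), al$tree, cfg)
  expect_identical(rr$ses_i, scratch$ses)
  expect_identical(rr$beta_mntd_i, scratch$beta_mntd)
  expect_identical(rr$rc_i, scratch$rc)
})

test_that("a target absent from the table is an exact no-op mapped to drift", {
  sim <- simulate_assembly("heterogeneous_selection", seed = 4, n_taxa = 15,
                           n_sites = 5, site_total = 300)
  cfg <- null_config(seed = 6, n_reps = 80)
  pr <- classify_communities(sim$community, sim$tree, cfg)
  ghost <- removal_target("ghost", c("NOPE1", "NOPE2"))
  expect_warning(
    att <- attribute_taxa(sim$community, sim$tree, list(ghost), cfg, pairs = pr),
    "not in the table")
  out <- att$outcomes
  expect_identical(out$ses_i, pr$ses)
  expect_identical(out$rc_i, pr$rc)
  ok <- out$status == "ok"
  expect_true(all(out$process[ok] == "drift"))
  row <- att$attribution
  expect_equal(row$drift, 1)
  expect_equal(row$heterogeneous_selection + row$homogeneous_selection +
                 row$dispersal_limitation + row$homogenizing_dispersal, 0)
})

test_that("removal emptying a site flags its pairs inapplicable", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix(c(4, 0, 0, 0,
                1, 2, 1, 0,
                0, 1, 2, 2), 3, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("A", "B", "C", "D")))
  cfg <- null_config(seed = 2, n_reps = 20)
  rr <- remove_and_recompute(m, tr, removal_target("A", "A"), cfg)
  s1 <- rr$site_a == "S1" | rr$site_b == "S1"
  expect_true(all(rr$status_i[s1] == "inapplicable"))
  expect_true(all(is.na(rr$ses_i[s1])))
  expect_true(all(rr$status_i[!s1] != "inapplicable"))
  att <- suppressWarnings(
    attribute_taxa(m, tr, list(removal_target("A", "A")), cfg))
  expect_identical(att$attribution$n_evaluable,
                   sum(att$outcomes$status == "ok"))
})

test_that("attribution rows are fractions over evaluable pairs summing to 1", {
  sim <- simulate_assembly("heterogeneous_selection", seed = 31, n_taxa = 25,
                           n_sites = 6, site_total = 400,
                           divergent_taxon = TRUE)
  cfg <- null_config(seed = 17, n_reps = 99)
  targets <- taxon_targets(sim$community)[1:6]
  att <- attribute_taxa(sim$community, sim$tree, targets, cfg)
  a <- att$attribution
  procs <- assembly_processes()
  sums <- rowSums(a[, procs])
  expect_true(all(abs(sums[a$n_evaluable > 0] - 1) < 1e-9))
  expect_true(all(a[, procs] >= 0 & a[, procs] <= 1, na.rm = TRUE))
})

test_that("group targets from a taxonomy remove all members simultaneously", {
  sim <- simulate_assembly("drift", seed = 9, n_taxa = 12, n_sites = 4,
                           site_total = 300)
  taxa <- colnames(sim$community)
  tax <- data.frame(phylum = rep(c("P1", "P2"), length.out = length(taxa)),
                    row.names = taxa)
  targets <- taxonomy_targets(tax, "phylum", sim$community)
  expect_named(targets, c("P1", "P2"))
  expect_setequal(c(targets$P1$taxa, targets$P2$taxa), taxa)
  cfg <- null_config(seed = 3, n_reps = 30)
  att <- attribute_taxa(sim$community, sim$tree, targets, cfg)
  # group removal equals removing the member set in one step
  rr <- remove_and_recompute(sim$community, sim$tree, targets$P1, cfg,
                             rc_pair_ids = integer(0))
  expect_identical(att$outcomes$ses_i[att$outcomes$target_id == "P1"],
                   rr$ses_i)
})

test_that("stronger trait divergence never weakens the causal taxon's signal", {
  # effect sizes stay below the monoculture threshold: once the divergent
  # taxon is the only member of the extreme site, removing it empties the
  # site and the signal-bearing pairs become inapplicable by design
  fracs <- vapply(c(0.2, 0.5, 0.9), function(dv) {
    sim <- simulate_assembly("heterogeneous_selection", seed = 47, n_taxa = 30,
                             n_sites = 8, site_total = 1000,
                             divergent_taxon = TRUE, divergence = dv)
    cfg <- null_config(seed = 29, n_reps = 199)
    pr <- classify_communities(sim$community, sim$tree, cfg)
    tg <- removal_target(sim$divergent_taxon, sim$divergent_taxon)
    att <- attribute_taxa(sim$community, sim$tree, list(tg), cfg, pairs = pr)
    att$attribution$heterogeneous_selection
  }, numeric(1))
  expect_true(all(diff(fracs) >= -1e-9))
})
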