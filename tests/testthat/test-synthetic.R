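rb <- builtin_rulebook()

test_that("generate_profiles plants valid, closed, disjoint profiles", {
  pr <- generate_profiles(rb, 4, 3, seed = 7)
  expect_length(pr, 4)
  for (p in pr) {
    expect_length(p$trait_ids, 3)
    # complement satisfies exactly the planted traits
    sat <- magtraits:::satisfied_traits(p$gene_complement, rb)
    expect_setequal(sat, p$trait_ids)
  }
  comps <- lapply(pr, `[[`, "gene_complement")
  for (i in 1:4) for (j in seq_len(i - 1))
    expect_length(intersect(comps[[i]], comps[[j]]), 0)

  # deterministic per seed
  expect_equal(generate_profiles(rb, 4, 3, seed = 7), pr)
  expect_false(identical(generate_profiles(rb, 4, 3, seed = 8), pr))

  # impossible requests error
  expect_error(generate_profiles(rb, 4, 100, seed = 1),
               class = "magtraits_input_error")
  expect_error(generate_profiles(rb, 10, 3, seed = 1), "only")
})

test_that("subgroup_profile enforces its invariants", {
  p <- subgroup_profile("s1", c("asr", "cbb_cycle"), rb)
  expect_setequal(p$gene_complement,
                  c("sat", "cysC", "cysH", "rbcL", "rbcS", "prk"))
  expect_error(subgroup_profile("s1", "no_such_trait", rb),
               class = "magtraits_input_error")
  # respiratory_chain_complete's complement also satisfies the individual
  # complexes: rejected under closure checking, accepted without
  expect_error(subgroup_profile("s1", "respiratory_chain_complete", rb),
               "non-planted")
  expect_s3_class(subgroup_profile("s1", "respiratory_chain_complete", rb,
                                   check_closure = FALSE), "mag_profile")
})

test_that("simulate_genomes is reproducible and respects its edge cases", {
  pr <- generate_profiles(rb, 2, 2, seed = 9)
  cfg <- simulation_config(n_subgroups = 2, genomes_per_subgroup = 6,
                           traits_per_subgroup = 2, seed = 10)
  sim1 <- simulate_genomes(pr, cfg)
  sim2 <- simulate_genomes(pr, cfg)
  expect_identical(sim1$annotations$records, sim2$annotations$records)
  expect_identical(sim1$genomes, sim2$genomes)

  # adding genomes never reshuffles earlier genomes within a subgroup
  cfg_big <- simulation_config(n_subgroups = 2, genomes_per_subgroup = 9,
                               traits_per_subgroup = 2, seed = 10)
  big <- simulate_genomes(pr, cfg_big)
  g1 <- sim1$truth$genomes[["sg1_mag003"]]
  expect_identical(big$truth$genomes[["sg1_mag003"]], g1)

  # full completeness, zero contamination: annotations equal the complements
  perfect <- simulate_genomes(pr, simulation_config(
    n_subgroups = 2, genomes_per_subgroup = 3, traits_per_subgroup = 2,
    completeness_range = c(100, 100), contamination_rate = 0, seed = 4))
  for (gid in names(perfect$truth$genomes)) {
    tg <- perfect$truth$genomes[[gid]]
    syms <- perfect$annotations$records$symbol[
      perfect$annotations$records$genome_id == gid]
    comp <- pr[[as.integer(sub("sg(\\d).*", "\\1", gid))]]$gene_complement
    expect_setequal(syms, comp)
    expect_length(tg$dropped, 0)
    expect_length(tg$injected, 0)
  }

  # zero completeness: empty annotation table
  empty <- simulate_genomes(pr, simulation_config(
    n_subgroups = 2, genomes_per_subgroup = 3, traits_per_subgroup = 2,
    completeness_range = c(0, 0), contamination_rate = 0, seed = 4))
  expect_equal(nrow(empty$annotations$records), 0)

  # config validation
  expect_error(simulation_config(completeness_range = c(80, 120)),
               class = "magtraits_input_error")
  expect_error(simulation_config(contamination_rate = 1.2), "contamination_rate")
  expect_error(simulation_config(genomes_per_subgroup = 0), "positive")
  expect_error(simulate_genomes(pr, simulation_config(n_subgroups = 3)),
               "does not match")

  # truth bookkeeping: dropped and retained partition the complement,
  # injections are foreign
  for (gid in names(sim1$truth$genomes)) {
    tg <- sim1$truth$genomes[[gid]]
    comp <- pr[[as.integer(sub("sg(\\d).*", "\\1", gid))]]$gene_complement
    expect_setequal(c(tg$retained, tg$dropped), comp)
    expect_length(intersect(tg$injected, comp), 0)
  }
})

test_that("perfect simulations recover planted traits exactly", {
  pr <- generate_profiles(rb, 3, 2, seed = 21)
  sim <- simulate_genomes(pr, simulation_config(
    n_subgroups = 3, genomes_per_subgroup = 5, traits_per_subgroup = 2,
    completeness_range = c(100, 100), contamination_rate = 0, seed = 21))
  tm <- call_traits(filter_quality(sim$genomes), sim$annotations, rb)
  rec <- score_recovery(tm, sim$truth)
  expect_equal(rec$overall_accuracy, 1)
  planted <- unique(unlist(lapply(pr, `[[`, "trait_ids")))
  pt <- rec$per_trait
  expect_true(all(pt$sensitivity[pt$trait_id %in% planted] == 1))
  expect_true(all(pt$specificity[!is.na(pt$specificity)] == 1))
  # non-planted traits have undefined sensitivity (no positives planted)
  expect_true(all(is.na(pt$sensitivity[!pt$trait_id %in% planted])))
})

test_that("specificity is exactly 1 under zero contamination", {
  pr <- generate_profiles(rb, 3, 2, seed = 31)
  sim <- simulate_genomes(pr, simulation_config(
    n_subgroups = 3, genomes_per_subgroup = 10, traits_per_subgroup = 2,
    completeness_range = c(50, 98), contamination_rate = 0, seed = 31))
  tm <- call_traits(filter_quality(sim$genomes), sim$annotations, rb)
  rec <- score_recovery(tm, sim$truth)
  expect_true(all(rec$per_trait$fp == 0))
})

test_that("empirical sensitivity matches the binomial closed forms (small n)", {
  # 4-subunit complex under per-gene retention p: the call needs >2 of 4
  # subunits, so sensitivity = P(Bin(4,p) >= 3) = 4 p^3 (1-p) + p^4
  p <- 0.7
  pr <- list(subgroup_profile("subgroup 1", "sulfhydrogenase", rb))
  sim <- simulate_genomes(pr, simulation_config(
    n_subgroups = 1, genomes_per_subgroup = 500, traits_per_subgroup = 1,
    completeness_range = c(100 * p, 100 * p), contamination_rate = 0, seed = 6))
  tm <- call_traits(filter_quality(sim$genomes), sim$annotations, rb)
  rec <- score_recovery(tm, sim$truth)
  sens <- rec$per_trait$sensitivity[rec$per_trait$trait_id == "sulfhydrogenase"]
  expected <- 4 * p^3 * (1 - p) + p^4
  se <- sqrt(expected * (1 - expected) / 500)
  expect_lt(abs(sens - expected), 3 * se)
})

test_that("raising the completeness floor never lowers mean sensitivity", {
  pr <- list(subgroup_profile("subgroup 1", "asr", rb))
  mean_sens <- function(lo, seed) {
    sim <- simulate_genomes(pr, simulation_config(
      n_subgroups = 1, genomes_per_subgroup = 300, traits_per_subgroup = 1,
      completeness_range = c(lo, 98), contamination_rate = 0, seed = seed))
    tm <- call_traits(filter_quality(sim$genomes, min_completeness = 1),
                      sim$annotations, rb)
    rec <- score_recovery(tm, sim$truth)
    rec$per_trait$sensitivity[rec$per_trait$trait_id == "asr"]
  }
  for (seed in c(2, 3)) {
    s_lo <- mean_sens(50, seed)
    s_hi <- mean_sens(85, seed)
    expect_gte(s_hi, s_lo)
  }
})

test_that("truth JSON round-trips through the serializer", {
  pr <- generate_profiles(rb, 2, 2, seed = 12)
  sim <- simulate_genomes(pr, simulation_config(
    n_subgroups = 2, genomes_per_subgroup = 3, traits_per_subgroup = 2, seed = 12))
  path <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- read_truth_json(path)
  expect_equal(names(back$genomes), names(sim$truth$genomes))
  for (gid in names(back$genomes)) {
    expect_equal(back$genomes[[gid]]$planted_traits,
                 sim$truth$genomes[[gid]]$planted_traits)
    expect_equal(back$genomes[[gid]]$retained, sim$truth$genomes[[gid]]$retained)
  }
  expect_equal(back$config$seed, sim$truth$config$seed)

  # scoring a matrix with unknown genomes errors
  tm <- call_traits(filter_quality(sim$genomes), sim$annotations, rb)
  tm$genome_ids[1] <- "ghost"
  rownames(tm$values)[1] <- "ghost"
  expect_error(score_recovery(tm, sim$truth), class = "magtraits_input_error")
})
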