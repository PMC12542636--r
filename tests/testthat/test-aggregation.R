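rb <- builtin_rulebook()

# small called matrix shared by the aggregation tests: two subgroups with
# planted, non-overlapping gene sets
make_small_tm <- function() {
  ann <- make_annotations(rbind(
    ann_df("a1", c("sat", "cysC", "cysH")),
    ann_df("a2", c("sat", "cysC", "cysH", "adh")),
    ann_df("a3", c("adh")),
    ann_df("b1", c("rbcL", "prk")),
    ann_df("b2", c("rbcL", "prk")),
    ann_df("b3", c("nosZ"))))
  gs <- filter_quality(make_genomes(
    meta_df(c("a1", "a2", "a3", "b1", "b2", "b3"),
            subgroup = rep(c("subgroup 1", "subgroup 2"), each = 3))))
  list(tm = call_traits(gs, ann, rb), gs = gs)
}

test_that("three-state classification matches the >=50% / >0% / 0 partition", {
  expect_equal(trait_state(5, 10), "MAJOR")   # exactly half counts as MAJOR
  expect_equal(trait_state(1, 10), "MINOR")
  expect_equal(trait_state(0, 10), "ABSENT")
  expect_equal(trait_state(10, 10), "MAJOR")
  expect_error(trait_state(3, 2), class = "magtraits_input_error")
})

test_that("summarize_subgroups produces one consistent row per subgroup x trait", {
  x <- make_small_tm()
  summ <- summarize_subgroups(x$tm, x$gs)
  expect_equal(nrow(summ), 2 * length(x$tm$trait_ids))
  expect_true(all(summ$n_present <= summ$n_total))

  asr1 <- summ[summ$subgroup == "subgroup 1" & summ$trait_id == "asr", ]
  expect_equal(asr1$n_present, 2)
  expect_equal(asr1$state, "MAJOR")
  asr2 <- summ[summ$subgroup == "subgroup 2" & summ$trait_id == "asr", ]
  expect_equal(asr2$state, "ABSENT")
  n2o2 <- summ[summ$subgroup == "subgroup 2" & summ$trait_id == "n2o_reduction", ]
  expect_equal(n2o2$state, "MINOR")

  # unlabeled genomes error unless pooled
  gs2 <- x$gs
  gs2$subgroup[1] <- NA
  expect_error(summarize_subgroups(x$tm, gs2), class = "magtraits_input_error")
  pooled <- summarize_subgroups(x$tm, gs2, default_unassigned = TRUE)
  expect_true("unassigned" %in% pooled$subgroup)
})

test_that("count_by_subgroup tallies match column sums and raw calls", {
  x <- make_small_tm()
  for (tr in c("asr", "ethanol_utilization", "cbb_cycle", "glycolysis")) {
    counts <- count_by_subgroup(x$tm, x$gs, tr)
    expect_equal(sum(counts), sum(x$tm$values[, tr]))
    # independent tally straight from the stored calls
    manual <- table(factor(
      vapply(x$tm$calls[vapply(x$tm$calls, function(g) g[[tr]]$present, logical(1))],
             function(g) x$gs$subgroup[x$gs$genome_id == g[[tr]]$genome_id],
             character(1)),
      levels = names(counts)))
    expect_equal(unname(counts), as.integer(manual))
  }
  expect_equal(sum(count_by_subgroup(x$tm, x$gs, "glycolysis")), 0)
  expect_error(count_by_subgroup(x$tm, x$gs, "no_such_trait"),
               class = "magtraits_input_error")
})

test_that("cooccurrence builds the 2x2 table and flags exclusivity", {
  tm <- structure(list(
    genome_ids = paste0("g", 1:4), trait_ids = c("t1", "t2", "t3", "t4"),
    values = matrix(c(1, 1, 0, 0,
                      0, 0, 1, 1,
                      1, 1, 0, 0,
                      0, 0, 0, 0), nrow = 4,
                    dimnames = list(paste0("g", 1:4), c("t1", "t2", "t3", "t4")))),
    class = "mag_trait_matrix")
  storage.mode(tm$values) <- "integer"

  co <- cooccurrence(tm, "t1", "t2")
  expect_equal(co$n11, 0)
  expect_true(co$mutually_exclusive)
  expect_equal(co$jaccard, 0)

  ident <- cooccurrence(tm, "t1", "t3")
  expect_equal(ident$jaccard, 1)
  expect_false(ident$mutually_exclusive)

  # all-zero column: vacuity guard
  expect_false(cooccurrence(tm, "t1", "t4")$mutually_exclusive)

  # symmetry
  ab <- cooccurrence(tm, "t1", "t2")
  ba <- cooccurrence(tm, "t2", "t1")
  expect_equal(ab$n10, ba$n01)
  expect_equal(ab$n01, ba$n10)
  expect_equal(ab$n11, ba$n11)
  expect_equal(ab$n00, ba$n00)
  expect_equal(ab$jaccard, ba$jaccard)
  expect_equal(ab$mutually_exclusive, ba$mutually_exclusive)

  # table always partitions the genomes
  expect_equal(co$n11 + co$n10 + co$n01 + co$n00, length(tm$genome_ids))

  expect_error(cooccurrence(tm, "t1", "zz"), class = "magtraits_input_error")
})

test_that("clustering orders identical profiles adjacently and is deterministic", {
  tm <- structure(list(
    genome_ids = paste0("g", 1:3), trait_ids = c("t1", "t2", "t3"),
    values = matrix(c(1, 1, 0,
                      0, 0, 1,
                      1, 1, 0), nrow = 3, byrow = TRUE,
                    dimnames = list(paste0("g", 1:3), c("t1", "t2", "t3")))),
    class = "mag_trait_matrix")
  ord <- cluster_profiles(tm, "genomes")
  pos <- match(c(1, 3), ord$order)
  expect_equal(abs(diff(pos)), 1)  # identical rows g1, g3 adjacent
  expect_equal(ord$order, cluster_profiles(tm, "genomes")$order)

  # single item
  tm1 <- tm; tm1$values <- tm$values[1, , drop = FALSE]; tm1$genome_ids <- "g1"
  expect_equal(cluster_profiles(tm1, "genomes")$order, 1L)
})

test_that("merge history matches a hand-executed agglomeration on a 4x3 fixture", {
  # rows: r1=(0,0,0) r2=(0,0,1) r3=(1,1,1) r4=(1,1,0)
  # Euclidean distances: d12=d34=1, d14=d23=sqrt(2), d13=d24=sqrt(3).
  # Complete linkage: merge {1,2} at 1, {3,4} at 1, then both clusters at
  # max pairwise distance sqrt(3).
  vals <- matrix(c(0, 0, 0,
                   0, 0, 1,
                   1, 1, 1,
                   1, 1, 0), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("r", 1:4), paste0("t", 1:3)))
  tm <- structure(list(genome_ids = rownames(vals), trait_ids = colnames(vals),
                       values = vals), class = "mag_trait_matrix")
  ord <- cluster_profiles(tm, "genomes", "euclidean", "complete")
  expect_equal(ord$heights, c(1, 1, sqrt(3)))
  expect_equal(ord$merges[1, ], c(-1L, -2L))
  expect_equal(ord$merges[2, ], c(-3L, -4L))
  expect_equal(ord$merges[3, ], c(1L, 2L))

  # average linkage joins the two pairs at mean(sqrt(2), sqrt(3), ...) instead
  avg <- cluster_profiles(tm, "genomes", "euclidean", "average")
  expect_equal(avg$heights[3], mean(c(sqrt(2), sqrt(3), sqrt(3), sqrt(2))))

  # jaccard distance: identical all-zero profiles sit at distance 0
  vals0 <- rbind(vals, r5 = c(0, 0, 0))
  tm0 <- structure(list(genome_ids = rownames(vals0), trait_ids = colnames(vals0),
                        values = vals0), class = "mag_trait_matrix")
  jac <- cluster_profiles(tm0, "genomes", "jaccard", "complete")
  expect_equal(jac$heights[1], 0)  # r1 and r5
})

test_that("clustering tree topology is invariant to row permutation", {
  set.seed(33)
  vals <- matrix(rbinom(28, 1, 0.4), nrow = 7,
                 dimnames = list(paste0("g", 1:7), paste0("t", 1:4)))
  tm <- structure(list(genome_ids = rownames(vals), trait_ids = colnames(vals),
                       values = vals), class = "mag_trait_matrix")
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  tmp <- structure(list(genome_ids = rownames(vals)[perm],
                        trait_ids = colnames(vals),
                        values = vals[perm, ]), class = "mag_trait_matrix")
  a <- cluster_profiles(tm, "genomes")
  b <- cluster_profiles(tmp, "genomes")
  expect_equal(sort(a$heights), sort(b$heights))
  # cluster memberships agree after relabeling: cut both trees at every
  # height and compare the induced label partitions
  cut_partition <- function(o, h) {
    hc <- list(merge = o$merges, height = o$heights, order = o$order,
               labels = o$labels)
    class(hc) <- "hclust"
    grp <- stats::cutree(hc, h = h)
    unname(split(names(grp), grp))
  }
  for (h in a$heights) {
    pa <- lapply(cut_partition(a, h), sort)
    pb <- lapply(cut_partition(b, h), sort)
    expect_setequal(vapply(pa, paste, character(1), collapse = ","),
                    vapply(pb, paste, character(1), collapse = ","))
  }
})
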