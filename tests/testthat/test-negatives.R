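test_that("levenshtein distance has the standard edit-distance behaviour", {
  expect_equal(levenshtein("FEDLRLLSF", "FEDLRVLSF"), 1L)
  expect_equal(levenshtein("GILGFVFTL", "GILGFVFTL"), 0L)
  expect_equal(levenshtein("GILGFVFTL", ""), 9L)
  expect_equal(levenshtein("KITTEN", "SITTING"), 3L)
  expect_equal(levenshtein(c("AB", "CD"), c("AC", "CD")), c(1L, 0L))
})

test_that("partitioning is balanced and seed-reproducible", {
  ds <- toy_dataset(10)
  p <- partition_dataset(ds, k = 5, seed = 4)
  expect_equal(as.integer(table(p$partition)), rep(2L, 5))
  expect_identical(partition_dataset(ds, k = 5, seed = 4)$partition,
                   p$partition)
  big <- toy_dataset(100)
  a <- partition_dataset(big, k = 5, seed = 1)$partition
  b <- partition_dataset(big, k = 5, seed = 2)$partition
  expect_false(identical(a, b))
  expect_true(all(abs(diff(as.integer(table(a)))) <= 1))
  expect_error(partition_dataset(toy_dataset(3), k = 5), "fewer records")
})

test_that("peptides inside the distance threshold yield no swapped negatives", {
  close_peps <- c("FEDLRLLSF", "FEDLRVLSF")  # distance 1
  ds <- toy_dataset(10, peptides = close_peps)
  ds <- partition_dataset(ds, k = 5, seed = 1)
  warns <- capture_warnings(out <- generate_swapped_negatives(
    ds, negative_config()))
  expect_match(warns, "no eligible donor", all = TRUE)
  expect_length(warns, 2L)  # one per starved peptide
  expect_equal(sum(out$binder == 0), 0L)
})

test_that("swapped negatives respect partition, distance and uniqueness", {
  sim <- simulate_repertoire(sim_config(default_peptide_panel(30, 3),
                                        seed = 8))
  ds <- partition_dataset(sim$dataset, k = 5, seed = 2)
  cfg <- negative_config(swapped_ratio = 2, seed = 6)
  out <- generate_swapped_negatives(ds, cfg)
  neg <- out[out$binder == 0, ]
  expect_true(all(neg$negative_kind == "swapped"))
  # donor peptides are distant from the labeled peptide
  expect_true(all(levenshtein(neg$peptide, neg$source_peptide) >=
                    cfg$min_peptide_distance))
  # donors come from the same partition (donor partition is preserved)
  donor_part <- ds$partition[match(sub("_sw_.*", "", neg$record_id),
                                   ds$record_id)]
  expect_equal(neg$partition, donor_part)
  # no duplicate (donor, peptide) pairs
  expect_false(anyDuplicated(neg[c("record_id", "peptide")]) > 0)
  # positives pass through unchanged
  expect_identical(as.data.frame(out[out$binder == 1, ]) ,
                   as.data.frame(ds))
  # reproducible under the same seed
  expect_identical(generate_swapped_negatives(ds, cfg), out)
})

test_that("swapped-negative fallback uses the whole pool once", {
  # 2 peptides x 10 positives in one partition at ratio 5: the eligible pool
  # per peptide is only the 10 opposite positives, so each peptide receives
  # min(5 * 10, 10) = 10 negatives
  ds <- toy_dataset(20)
  ds$partition <- 1L
  out <- generate_swapped_negatives(ds, negative_config(swapped_ratio = 5,
                                                        seed = 1))
  neg <- out[out$binder == 0, ]
  expect_equal(as.integer(table(neg$peptide)), c(10L, 10L))
  # achieved ratio is pool / positives, not the requested ratio
  expect_equal(nrow(neg) / sum(ds$binder == 1), 1)
})

test_that("negative controls are sampled per peptide and partition", {
  sim <- simulate_repertoire(sim_config(default_peptide_panel(20, 2),
                                        seed = 3))
  pos <- partition_dataset(sim$dataset, k = 2, seed = 1)
  ctl <- toy_dataset(100, peptides = "AYHIPCGKE")
  ctl$record_id <- paste0("ctl", seq_len(nrow(ctl)))
  ctl <- partition_dataset(ctl, k = 2, seed = 2)
  cfg <- negative_config(control_ratio = 2, seed = 4)
  out <- sample_negative_controls(ctl, pos, cfg)
  expect_true(all(out$binder == 0))
  expect_true(all(out$negative_kind == "control"))
  # per (peptide, partition): ratio x positives controls
  tab <- table(out$peptide, out$partition)
  pos_tab <- table(pos$peptide, pos$partition)
  expect_equal(unclass(tab), unclass(pos_tab) * 2, ignore_attr = TRUE)
  # ratio 0 gives an empty result
  expect_equal(nrow(sample_negative_controls(ctl, pos,
                                             negative_config())), 0L)
  # scarcity: all controls used with a warning
  few <- ctl[1:3, ]
  class(few) <- c("tcr_dataset", "data.frame")
  warns <- capture_warnings(out2 <- sample_negative_controls(few, pos, cfg))
  expect_match(warns, "controls available", all = TRUE)
  expect_lte(nrow(out2), 2L * nrow(pos))
})

test_that("swapped plus control ratios reach the combined 1:5 design", {
  sim <- simulate_repertoire(sim_config(default_peptide_panel(20, 3),
                                        seed = 3))
  pos <- partition_dataset(sim$dataset, k = 2, seed = 1)
  ctl <- toy_dataset(200, peptides = "KDEYHWMRV")
  ctl$record_id <- paste0("ctl", seq_len(nrow(ctl)))
  ctl <- partition_dataset(ctl, k = 2, seed = 2)
  cfg <- negative_config(swapped_ratio = 2, control_ratio = 3,
                         min_peptide_distance = 3, seed = 9)
  sw <- generate_swapped_negatives(pos, cfg)
  nc <- sample_negative_controls(ctl, pos, cfg)
  n_pos <- sum(pos$binder == 1)
  n_neg <- sum(sw$binder == 0) + nrow(nc)
  # the achievable swapped count per (peptide, partition) is capped by the
  # donor pool; expected totals follow from the partition composition
  comp <- table(pos$peptide, pos$partition)
  expect_swapped <- sum(vapply(rownames(comp), function(p)
    sum(vapply(colnames(comp), function(g)
      min(ceiling(2 * comp[p, g]), sum(comp[rownames(comp) != p, g])),
      numeric(1))), numeric(1)))
  expect_equal(sum(sw$binder == 0), expect_swapped)
  expect_equal(nrow(nc), 3 * n_pos)
  expect_equal(n_neg / n_pos, 5, tolerance = 0.11)
})
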