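make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(mouse_id = r[[1]], week = as.numeric(r[[2]]), locus_id = r[[3]],
               position = as.numeric(r[[4]]), ref = r[[5]], alt = r[[6]],
               frequency = as.numeric(r[[7]]), stringsAsFactors = FALSE)))
}

test_that("variant TSV reader validates its input", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- make_calls(list("m1", 1, "geneA", 100, "C", "T", 0.4),
                   list("m1", 1, "geneB", 200, "G", "A", 0.9),
                   list("m2", 1, "geneA", 100, "C", "T", 1.0))
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_variant_table(tsv, "tsv")
  expect_equal(nrow(back), 3)
  expect_equal(back$frequency, c(0.4, 0.9, 1.0))

  bad <- df; bad$frequency[1] <- 1.2
  write.table(bad, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_variant_table(tsv, "tsv"), "frequency outside")

  dup <- rbind(df, df[1, ])
  write.table(dup, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_variant_table(tsv, "tsv"), "duplicate")
})

test_that("GenomeDiff subset reader picks up SNP/INS/DEL with frequencies", {
  gd <- withr::local_tempfile(fileext = ".gd")
  writeLines(c(
    "#=GENOME_DIFF 1.0",
    "SNP\t1\t10\tref\t3009211\tT\tfrequency=0.373\tgene_name=mprA_upstream",
    "SNP\t2\t11\tref\t500\tA\tfrequency=1",
    "INS\t3\t12\tref\t900\tGG\tfrequency=0.21",
    "DEL\t4\t13\tref\t1200\t2\tfrequency=0.05",
    "MOB\t5\t14\tref\t1500\tIS1\tfrequency=0.4",
    "RA\t6\t.\tref\t3009211\t0\tC\tT"), gd)
  calls <- read_variant_table(gd, "genomediff-subset", mouse_id = "m1", week = 12)
  expect_equal(nrow(calls), 4)  # MOB excluded; RA (no frequency=) excluded
  snp <- calls[calls$position == 3009211, ]
  expect_equal(snp$frequency, 0.373)
  expect_equal(snp$locus_id, "mprA_upstream")
})

test_that("inoculum subtraction keys on (position, alt)", {
  sample <- make_calls(list("m1", 12, "a", 10, "C", "T", 0.9),
                       list("m1", 12, "b", 20, "G", "A", 0.3))
  inoc <- data.frame(inoculum_id = "i1", locus_id = "a", position = 10,
                     ref = "C", alt = "T", frequency = 0.5)
  out <- subtract_inoculum(sample, inoc)
  expect_equal(out$position, 20)
  expect_equal(out$frequency, 0.3)  # frequencies unchanged

  # sample subset of inoculum -> empty
  expect_equal(nrow(subtract_inoculum(sample[1, ], inoc)), 0)

  # same position, different alt allele is retained (C>T vs C>A)
  inoc_ca <- transform(inoc, alt = "A")
  expect_equal(nrow(subtract_inoculum(sample, inoc_ca)), 2)

  # idempotent, never grows
  once <- subtract_inoculum(sample, inoc)
  expect_identical(subtract_inoculum(once, inoc), once)
  expect_lte(nrow(once), nrow(sample))
})

test_that("frequency threshold respects inclusivity", {
  calls <- make_calls(list("m1", 1, "a", 1, "C", "T", 0.049),
                      list("m1", 1, "b", 2, "C", "T", 0.05),
                      list("m1", 1, "c", 3, "C", "T", 0.051))
  kept <- apply_frequency_threshold(calls, variant_filter_config())
  expect_equal(kept$frequency, c(0.05, 0.051))
  strict <- apply_frequency_threshold(calls,
                                      variant_filter_config(inclusive = FALSE))
  expect_equal(strict$frequency, 0.051)
  expect_equal(nrow(apply_frequency_threshold(calls[0, ],
                                              variant_filter_config())), 0)
  # idempotence
  expect_identical(apply_frequency_threshold(kept, variant_filter_config()),
                   kept)
  expect_error(variant_filter_config(0), "min_frequency")
})

test_that("de-novo counts cover sampled mouse-weeks", {
  calls <- make_calls(list("m1", 12, "a", 1, "C", "T", 0.2),
                      list("m1", 12, "b", 2, "C", "T", 0.3),
                      list("m1", 12, "c", 3, "C", "T", 0.4))
  cnt <- count_de_novo(calls)
  expect_equal(cnt$n_mutations, 3)
  grid <- expand.grid(mouse_id = c("m1", "m2"), week = c(8, 12),
                      stringsAsFactors = FALSE)
  cnt2 <- count_de_novo(calls, grid)
  expect_equal(nrow(cnt2), 4)
  expect_equal(sum(cnt2$n_mutations), 3)
  expect_equal(cnt2$n_mutations[cnt2$mouse_id == "m2"], c(0, 0))
})

test_that("parallelism requires two mice with different inocula", {
  cohort <- data.frame(mouse_id = c("m1", "m2", "m3"),
                       genotype = c("WT", "WT", "KO"),
                       inoculum_id = c("i1", "i1", "i2"),
                       experiment_id = c("Exp1", "Exp1", "Exp2"))
  same_inoc <- make_calls(list("m1", 12, "gene", 5, "C", "T", 0.5),
                          list("m2", 12, "gene", 9, "C", "A", 0.4))
  expect_false(detect_parallel_loci(same_inoc, cohort)$is_parallel)
  diff_inoc <- make_calls(list("m1", 12, "gene", 5, "C", "T", 0.5),
                          list("m3", 12, "gene", 9, "C", "A", 0.4))
  expect_true(detect_parallel_loci(diff_inoc, cohort)$is_parallel)
  single <- make_calls(list("m1", 12, "gene", 5, "C", "T", 0.5))
  expect_false(detect_parallel_loci(single, cohort)$is_parallel)
  stranger <- make_calls(list("mX", 12, "gene", 5, "C", "T", 0.5))
  expect_error(detect_parallel_loci(stranger, cohort), "absent from cohort")
})

test_that("parallel detection agrees with brute force on random inputs", {
  for (seed in 1:25) {
    set.seed(seed)
    n_mice <- sample(3:8, 1)
    cohort <- data.frame(
      mouse_id = paste0("m", seq_len(n_mice)),
      genotype = sample(c("WT", "KO"), n_mice, replace = TRUE),
      inoculum_id = paste0("i", sample(seq_len(max(2, n_mice %/% 2)),
                                       n_mice, replace = TRUE)),
      experiment_id = "Exp", stringsAsFactors = FALSE)
    n_calls <- sample(5:20, 1)
    calls <- data.frame(
      mouse_id = sample(cohort$mouse_id, n_calls, replace = TRUE),
      week = 12, locus_id = sample(paste0("L", 1:5), n_calls, replace = TRUE),
      position = seq_len(n_calls), ref = "C", alt = "T",
      frequency = runif(n_calls), stringsAsFactors = FALSE)
    got <- detect_parallel_loci(calls, cohort)
    want <- brute_force_parallel(calls, cohort)
    expect_equal(stats::setNames(got$is_parallel, got$locus_id),
                 want[got$locus_id], info = paste("seed", seed))
  }
})

test_that("persistence fractions count final-week mutations seen earlier", {
  calls <- make_calls(list("m1", 8, "a", 1, "C", "T", 0.5),
                      list("m1", 12, "a", 1, "C", "T", 0.6),
                      list("m1", 12, "b", 2, "C", "T", 0.4),
                      list("m1", 12, "c", 3, "C", "T", 0.3))
  tab <- persistence_table(calls, final_week = 12)
  expect_equal(tab$fraction, 1 / 3)
  expect_false(tab$undefined)

  # identical sets -> fraction 1
  eq <- make_calls(list("m1", 8, "a", 1, "C", "T", 0.5),
                   list("m1", 12, "a", 1, "C", "T", 0.6))
  expect_equal(persistence_table(eq, 12)$fraction, 1)

  # empty final set -> undefined flag
  mt <- make_calls(list("m1", 8, "a", 1, "C", "T", 0.5),
                   list("m2", 12, "b", 2, "C", "T", 0.4))
  t1 <- persistence_table(mt, 12)
  expect_true(t1$undefined[t1$mouse_id == "m1"])
  expect_true(is.na(t1$fraction[t1$mouse_id == "m1"]))
  expect_error(persistence_table(calls, 16), "not sampled")
})

test_that("locus frequency matrix aggregates by maximum", {
  calls <- make_calls(list("m1", 12, "a", 1, "C", "T", 0.2),
                      list("m1", 12, "a", 5, "G", "A", 0.6),
                      list("m2", 12, "b", 2, "C", "T", 0.4))
  m <- locus_frequency_matrix(calls)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["m1", "a"], 0.6)   # max of 0.2 and 0.6
  expect_equal(m["m1", "b"], 0)
  expect_equal(m["m2", "b"], 0.4)
  z <- locus_frequency_matrix(calls[0, ], mice = c("m1", "m2"),
                              loci = c("a", "b"))
  expect_true(all(z == 0))
})
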