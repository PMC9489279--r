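test_that("Ct tables read, validate and round-trip", {
  df <- rbind(ct_row("S1", c(30, 32)), ct_row("S2", c(NA, 40)),
              ct_row("none", c(35, 34, NA), role = "benchmark4",
                     species = "none"))
  tab <- ctTable(df)
  expect_s4_class(tab, "CtTable")
  expect_equal(nrow(ctRecords(tab)), 7)
  expect_equal(sum(is.na(ctRecords(tab)$ct)), 2)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeCtTable(tab, path)
  back <- readCtTable(path)
  expect_equal(ctRecords(back)$ct, ctRecords(tab)$ct, tolerance = 1e-10)
  expect_equal(ctRecords(back)$role, ctRecords(tab)$role)

  # "ND" marks non-detections in text files
  lines <- c("strain,species,block,replicate,role,ct",
             "S1,S1,1,1,experimental,31.2",
             "S1,S1,1,2,experimental,ND")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path2)
  tab2 <- suppressWarnings(readCtTable(path2))
  expect_true(is.na(ctRecords(tab2)$ct[2]))

  # row-level errors carry the row number
  bad <- ct_row("S1", c(30, 45))
  expect_error(ctTable(bad), "row 2")
  bad2 <- rbind(ct_row("S1", 30), ct_row("S1", 31, replicate = 1))
  expect_error(ctTable(bad2), "duplicate")
  bad3 <- ct_row("S1", 30, role = "mystery")
  expect_error(ctTable(bad3), "unknown role")
})

test_that("within-strain sd averages per-strain variances", {
  mk <- function(df) suppressWarnings(ctTable(df))
  tab <- mk(rbind(ct_row("A", c(30, 32)), ct_row("B", c(NA, NA))))
  # variances {2, 0} (undetected -> 40), mean 1, sqrt = 1
  expect_equal(suppressMessages(withinStrainSd(tab)), 1)

  # identical replicates give zero spread
  tab2 <- mk(rbind(ct_row("A", c(30, 30, 30))))
  expect_equal(withinStrainSd(tab2), 0)

  # singleton strains are excluded from the mean
  tab3 <- mk(rbind(ct_row("A", c(30, 32)), ct_row("C", 20)))
  expect_equal(suppressMessages(withinStrainSd(tab3)), sqrt(2))
  expect_error(withinStrainSd(mk(ct_row("C", 20))), ">= 2")

  # a block with experimental rows but no benchmark-4 rows is flagged
  expect_warning(ctTable(ct_row("A", c(30, 32))), "benchmark4")
})

test_that("threshold derivation uses the most-virus benchmark Ct", {
  tab <- ctTable(rbind(
    ct_row("S1", c(30, 31)),
    ct_row("none", c(35, 34, NA), role = "benchmark4", species = "none"),
    ct_row("none", c(22, 21.5, 22.3), role = "benchmark5", species = "none")))
  thr <- deriveThreshold(tab, sigmaW = 2)
  expect_equal(thr$benchmarkMaxVirusCt, 34)  # min detected Ct = most virus
  expect_equal(thr$threshold, 32)
  # zero spread: threshold equals the benchmark minimum
  expect_equal(deriveThreshold(tab, 0)$threshold, 34)
  # benchmark-5 alternative ignores sigma_w
  expect_equal(deriveThreshold(tab, 2, benchmark = 5)$threshold, 21.5)
  # translation equivariance
  rec <- ctRecords(tab)
  rec$ct <- rec$ct + 3
  expect_equal(deriveThreshold(ctTable(rec), 2)$threshold,
               thr$threshold + 3)
  # no detected benchmark wells -> error
  tab2 <- ctTable(rbind(ct_row("S1", 30),
                        ct_row("none", NA, role = "benchmark4",
                               species = "none")))
  expect_error(deriveThreshold(tab2, 2), "benchmark4")
})

test_that("susceptibility calls use strict Ct < tau on experimental rows", {
  tab <- ctTable(rbind(
    ct_row("S1", c(35, 36, 28)),
    ct_row("S2", c(NA, NA, NA)),
    ct_row("S3", c(29.5, 31, 33)),
    ct_row("none", 33.6, role = "benchmark4", species = "none")))
  calls <- callSusceptibility(tab, 29.5)
  expect_equal(calls$n_infected[calls$strain == "S1"], 1)
  expect_true(calls$susceptible[calls$strain == "S1"])
  expect_false(calls$susceptible[calls$strain == "S2"])
  # equality with the threshold is not infection
  expect_equal(calls$n_infected[calls$strain == "S3"], 0)
  # benchmark rows never get a call
  expect_false("none" %in% calls$strain)

  # monotone in tau: raising tau never decreases counts
  taus <- c(20, 25, 29.5, 35, 39.9)
  counts <- sapply(taus, function(t) callSusceptibility(tab, t)$n_infected)
  for (i in seq_len(nrow(counts)))
    expect_true(all(diff(counts[i, ]) >= 0))

  # undetected (imputed 40) can never be infected for tau < 40
  expect_equal(callSusceptibility(tab, 39.99)$n_infected[2], 0)
})

test_that("benchmark summaries report per-role moments of detected wells", {
  tab <- ctTable(rbind(
    ct_row("S1", 30),
    ct_row("none", c(38, 39, NA), role = "benchmark4", species = "none"),
    ct_row("none", c(22, 22), role = "benchmark5", species = "none")))
  s <- suppressWarnings(summarizeBenchmarks(tab))
  b4 <- s[s$role == "benchmark4", ]
  expect_equal(b4$n_detected, 2)
  expect_equal(b4$mean_ct, 38.5)
  expect_equal(s$sd_ct[s$role == "benchmark5"], 0)
  expect_warning(summarizeBenchmarks(tab), "absent")

  tab1 <- ctTable(rbind(ct_row("none", 38, role = "benchmark4",
                               species = "none")))
  s1 <- suppressWarnings(summarizeBenchmarks(tab1))
  expect_true(is.na(s1$sd_ct[s1$role == "benchmark4"]))
})

test_that("transmission scores follow the passage-detection rule", {
  expect_equal(scoreTransmission(FALSE), 0L)
  expect_equal(scoreTransmission(c(TRUE, FALSE)), 1L)
  expect_equal(scoreTransmission(c(TRUE, TRUE, TRUE, FALSE)), 2L)
  expect_equal(scoreTransmission(rep(TRUE, 6)), 3L)
  expect_equal(scoreTransmission(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)), 2L)
  expect_error(scoreTransmission(c(TRUE, TRUE)), "truncated")
  expect_error(scoreTransmission(logical(0)))
})

test_that("every valid detection sequence maps to exactly one score", {
  # brute force over all boolean sequences of length 1..6
  for (len in 1:6) {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), len))
    for (r in seq_len(nrow(grid))) {
      d <- as.logical(grid[r, ])
      truncated <- len < 6 && d[len]
      if (truncated && d[1]) {
        expect_error(scoreTransmission(d), "truncated")
      } else {
        s <- scoreTransmission(d)
        expect_true(s %in% 0:3)
        # anchor points of the partition
        expect_identical(s == 0L, !d[1])
        if (s >= 2L) expect_true(d[1] && d[2])
        if (len == 6) expect_identical(s == 3L, d[1] && d[2] && d[6])
      }
    }
  }
})

test_that("trajectory tables are scored per line", {
  traj <- rbind(
    data.frame(line_id = "L1", strain = "S1", passage = 0:5,
               detected = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
               passage0_ct = 21),
    data.frame(line_id = "L2", strain = "S2", passage = 0:1,
               detected = c(TRUE, FALSE), passage0_ct = 28),
    data.frame(line_id = "L3", strain = "S3", passage = 0,
               detected = FALSE, passage0_ct = NA))
  sc <- scoreTransmissionTable(traj)
  expect_equal(sc$score[match(c("L1", "L2", "L3"), sc$line_id)],
               c(3L, 1L, 0L))

  path <- withr::local_tempfile(fileext = ".tsv")
  out <- traj
  out$detected <- as.integer(out$detected)
  out$passage0_ct[is.na(out$passage0_ct)] <- "ND"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readTrajectories(path)
  expect_equal(scoreTransmissionTable(back)$score, sc$score)
})
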