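test_that("CSV loading validates schema and drops bad rows listwise", {
  cat39 <- defaultItemCatalog()
  good <- as.data.frame(matrix(1L, 3, 39, dimnames = list(NULL, cat39$item_id)))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(good, f, row.names = FALSE)
  rm <- loadResponses(f)
  expect_identical(dim(rm), c(3L, 39L))

  bad <- rbind(good, good[1, ])
  bad[4, "S1"] <- 4L
  write.csv(bad, f, row.names = FALSE)
  expect_message(rm2 <- loadResponses(f), "dropped 1 row")
  expect_identical(nRespondents(rm2), 3L)

  withNA <- good; withNA[2, "G3"] <- NA
  write.csv(withNA, f, row.names = FALSE)
  expect_message(rm3 <- loadResponses(f), "dropped 1 row")
  expect_identical(nRespondents(rm3), 2L)

  unknown <- cbind(good, bogus = 1L)
  write.csv(unknown, f, row.names = FALSE)
  expect_error(loadResponses(f), "bogus")

  missingCol <- good[, -1]
  write.csv(missingCol, f, row.names = FALSE)
  expect_error(loadResponses(f), "S1")

  allBad <- good; allBad[] <- 9L
  write.csv(allBad, f, row.names = FALSE)
  expect_error(suppressMessages(loadResponses(f)), "no rows")
})

test_that("scale totals sum the right items and are additive", {
  ids <- c(paste0("G", 1:7), "P1", "P2", "S1")
  v <- matrix(0L, 3, 10)
  v[2, 1:7] <- 3L                      # GAD-7 maximum
  v[3, 8:9] <- c(1L, 2L)               # PHQ-2 (1, 2)
  rm <- rmFromValues(v, ids)
  expect_identical(scaleTotal(rm, "GAD7"), c(0L, 21L, 0L))
  expect_identical(scaleTotal(rm, "PHQ2"), c(0L, 0L, 3L))

  rm2 <- randomResponses(40, ids, seed = 7)
  split1 <- rowSums(responseValues(rm2)[, paste0("G", 1:3)])
  split2 <- rowSums(responseValues(rm2)[, paste0("G", 4:7)])
  expect_identical(scaleTotal(rm2, "GAD7"), as.integer(split1 + split2))
  expect_error(scaleTotal(rm2[, c("S1", "P1", "P2")], "GAD7"), "GAD7")
})

test_that("screening counts respect cut-offs and row order", {
  ids <- c(paste0("G", 1:7), "P1", "P2")
  v <- matrix(0L, 5, 9)
  v[1, 1:4] <- 1L                      # GAD-7 total 4: below cut-off
  v[2, 1:5] <- 1L                      # total 5: positive
  v[3, 1:7] <- 3L                      # total 21: positive
  v[4, 8] <- 1L                        # PHQ-2 total 1: below
  v[5, 8:9] <- 1L                      # total 2: positive
  rm <- rmFromValues(v, ids)
  g <- screeningPrevalence(rm, "GAD7")
  expect_identical(g@positives, 2L)
  expect_equal(prevalencePct(g), 40)
  p <- screeningPrevalence(rm, "PHQ2")
  expect_identical(p@positives, 1L)

  shuffled <- rm[c(3, 5, 1, 4, 2), ]
  expect_identical(screeningPrevalence(shuffled, "GAD7")@positives, 2L)
  # brute force over respondents
  expect_identical(g@positives,
                   sum(vapply(seq_len(5), function(i)
                     sum(v[i, 1:7]) >= 5L, logical(1))))
})

test_that("symptom frequency counts endorsement and is monotone", {
  v <- cbind(S1 = c(0L, 1L, 2L, 3L), S2 = c(0L, 0L, 0L, 0L),
             S3 = c(3L, 3L, 3L, 3L))
  rm <- rmFromValues(v)
  tb <- symptomFrequency(rm)
  tb <- tb[match(c("S1", "S2", "S3"), tb$item_id), ]
  expect_equal(tb$frequency_pct, c(75, 0, 100))
  expect_equal(tb$mean, c(1.5, 0, 3))
  expect_equal(tb$sd[2], 0)

  # an endorsing respondent never lowers the frequency
  v2 <- rbind(v, c(3L, 1L, 3L))
  tb2 <- symptomFrequency(rmFromValues(v2))
  tb2 <- tb2[match(tb$item_id, tb2$item_id), ]
  expect_true(all(tb2$frequency_pct >= tb$frequency_pct))
})

test_that("Cronbach's alpha matches its variance-decomposition oracle", {
  # identical columns: perfect consistency
  v <- cbind(A = c(0L, 1L, 2L, 3L), B = c(0L, 1L, 2L, 3L))
  colnames(v) <- c("S1", "S2")
  expect_equal(cronbachAlpha(rmFromValues(v)), 1)

  # zero sample covariance between two items: alpha = 0
  v0 <- cbind(S1 = c(0L, 1L, 0L, 1L), S2 = c(0L, 0L, 1L, 1L))
  expect_equal(cronbachAlpha(rmFromValues(v0)), 0)

  # random fixture vs covariance-sum identity k/(k-1) (1 - tr(C)/sum(C))
  rm <- randomResponses(50, paste0("S", 1:5), seed = 42)
  C <- cov(responseValues(rm))
  oracle <- 5 / 4 * (1 - sum(diag(C)) / sum(C))
  expect_equal(cronbachAlpha(rm), oracle, tolerance = 1e-12)

  # invariant under item relabeling
  expect_equal(cronbachAlpha(rm, c("S3", "S1", "S5", "S2", "S4")),
               cronbachAlpha(rm))

  const <- rmFromValues(cbind(S1 = rep(1L, 4), S2 = rep(2L, 4)))
  expect_error(cronbachAlpha(const), "variance")
})
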