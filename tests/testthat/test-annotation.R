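# Mark-point I/O, bifocal pair extraction, augmentation and the inference
# lattice.

makeMarks <- function(n, caseId = "c1", tileId = "t1", label = "positive") {
  data.frame(case_id = caseId, tile_id = tileId,
             x = sample(32:120, n, replace = TRUE),
             y = sample(32:120, n, replace = TRUE),
             label = label, stringsAsFactors = FALSE)
}

test_that("marks round-trip through CSV fieldwise", {
  set.seed(1)
  marks <- rbind(makeMarks(120), makeMarks(80, label = "negative"))
  p <- withr::local_tempfile(fileext = ".csv")
  writeMarks(marks, p)
  back <- readMarks(p)
  expect_equal(back[markOrder <- order(back$x, back$y), ],
               marks[order(marks$x, marks$y), ], ignore_attr = TRUE)
})

test_that("an empty file with header reads as zero marks", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeMarks(makeMarks(1)[0, ], p)
  expect_equal(nrow(readMarks(p)), 0L)
})

test_that("malformed rows are rejected with their location", {
  p <- withr::local_tempfile(fileext = ".csv")
  m <- makeMarks(3)
  m$x[2] <- -1
  writeMarks(m, p)
  expect_error(readMarks(p), "row\\(s\\) 2")
  m <- makeMarks(3)
  m$label[3] <- "maybe"
  writeMarks(m, p)
  expect_error(readMarks(p), "unknown label at row\\(s\\) 3")
  writeLines("case_id,tile_id,x\nc,t,1", p)
  expect_error(readMarks(p), "missing columns")
  expect_error(writeMarks(data.frame(x = 1), p), "missing columns")
})

test_that("bifocal crops use half-open windows and nest exactly", {
  g <- generateTile(tinySynth(tileWidth = 128L, tileHeight = 128L,
                              nCells = 2L))
  tile <- g$tile
  arr <- tileArray(tile)
  ps <- extractBifocalPair(tile, c(32, 32))
  expect_equal(widePatches(ps)[, , , 1], arr[1:64, 1:64, ])
  ps2 <- extractBifocalPair(tile, c(64, 72))
  expect_equal(widePatches(ps2)[17:48, 17:48, , 1],
               narrowPatches(ps2)[, , , 1])
  expect_error(extractBifocalPair(tile, c(31, 64)), "closer than")
  expect_error(extractBifocalPair(tile, c(64, 97)), "closer than")
})

test_that("training-set construction counts, skips borders, is deterministic", {
  cfg <- tinySynth(nCells = 6L, nNegatives = 6L)
  g <- generateTile(cfg)
  tiles <- list(g$tile)
  ps <- buildTrainingSet(tiles, g$marks, seed = 3)
  expect_equal(length(ps), nrow(g$marks))
  expect_equal(as.character(pairLabels(ps)), g$marks$label)

  aug <- buildTrainingSet(tiles, g$marks, augment = TRUE, variants = 3L,
                          seed = 3)
  expect_equal(length(aug), 4L * nrow(g$marks))
  aug2 <- buildTrainingSet(tiles, g$marks, augment = TRUE, variants = 3L,
                           seed = 3)
  expect_identical(widePatches(aug), widePatches(aug2))

  border <- g$marks
  border$x[1] <- 10L  # closer than 32 px to the tile edge
  expect_message(ps2 <- buildTrainingSet(tiles, border, seed = 3),
                 "border mark")
  expect_equal(length(ps2), nrow(g$marks) - 1L)
})

test_that("train and test case sets must be disjoint", {
  marks <- rbind(makeMarks(5, caseId = "a"), makeMarks(5, caseId = "b"))
  sp <- splitMarksByCase(marks, "a", "b")
  expect_equal(nrow(sp$train), 5L)
  expect_equal(nrow(sp$test), 5L)
  expect_error(splitMarksByCase(marks, c("a", "b"), "b"), "overlap")
})

test_that("inference lattice matches the closed form and brute force", {
  expect_equal(nrow(enumerateInferenceCentres(c(64, 64))), 1L)
  expect_equal(enumerateInferenceCentres(c(64, 64))[1, ],
               c(x = 32L, y = 32L))
  expect_equal(nrow(enumerateInferenceCentres(c(128, 128))), 49L)
  expect_equal(nrow(enumerateInferenceCentres(c(1000, 1000))), 8836L)
  expect_error(enumerateInferenceCentres(c(63, 128)), "smaller than")

  set.seed(2)
  for (i in 1:10) {
    W <- sample(64:400, 1); H <- sample(64:400, 1)
    cen <- enumerateInferenceCentres(c(W, H))
    expect_equal(unname(cen), unname(bruteCentres(W, H)))
    # lattice property: consecutive centres differ by the stride on one axis
    step <- diff(cen[, 1])
    expect_true(all(step == 10 | step < 0))
  }
})
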