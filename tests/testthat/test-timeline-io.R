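writeAnnCSV <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("readAnnotations parses and validates coder output", {
  path <- writeAnnCSV(data.frame(
    participant = "infant", dimension = "SM", main_code = 1, sub_code = 2,
    onset_s = 0.0, offset_s = 1.5))
  ann <- readAnnotations(path)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$sub_code, 2L)  # circular/repetitive action (banging etc.)

  ## SM main 0 takes no sub-code
  bad <- writeAnnCSV(data.frame(
    participant = "infant", dimension = "SM", main_code = 0, sub_code = 2,
    onset_s = 0.0, offset_s = 1.0))
  expect_error(readAnnotations(bad), "row 1.*SM main 0 takes no sub-code")

  ## empty file with header -> empty table
  empty <- writeAnnCSV(data.frame(
    participant = character(0), dimension = character(0),
    main_code = integer(0), sub_code = integer(0),
    onset_s = numeric(0), offset_s = numeric(0)))
  expect_equal(nrow(readAnnotations(empty)), 0)

  ## missing column named in the error
  noCol <- tempfile(fileext = ".csv")
  write.csv(data.frame(participant = "infant", dimension = "SE",
                       main_code = 1, onset_s = 0, offset_s = 1),
            noCol, row.names = FALSE)
  expect_error(readAnnotations(noCol), "sub_code")

  ## column mapping and TSV dialect
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(who = "adult", dimension = "C", main_code = 1,
                         sub_code = 5, start = 0, stop = 2),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  ann <- readAnnotations(tsv, columns = c(participant = "who",
                                          onset_s = "start",
                                          offset_s = "stop"))
  expect_equal(ann$offset_s, 2)
})

test_that("validateAnnotations enforces interval and code rules row-wise", {
  base <- data.frame(participant = "infant", dimension = "SE",
                     main_code = 1, sub_code = 1, onset_s = 0, offset_s = 1)
  expect_error(validateAnnotations(transform(base, offset_s = 0)),
               "onset_s < offset_s")
  expect_error(validateAnnotations(transform(base, dimension = "XX")),
               "unknown dimension")
  expect_error(validateAnnotations(transform(base, participant = "coder")),
               "unknown participant")
  expect_error(validateAnnotations(transform(base, main_code = 3)),
               "main_code")
  expect_error(validateAnnotations(transform(base, sub_code = 7)),
               "SE main 1 takes sub-codes \\{1,2\\}")
})

test_that("rasterization maps half-open intervals onto the frame grid", {
  ann <- data.frame(dimension = "SE", main_code = 1, sub_code = 1,
                    onset_s = 0, offset_s = 1)
  ann <- rbind(ann,
               data.frame(dimension = c("SM", "SM"), main_code = c(1, 0),
                          sub_code = c(1, NA), onset_s = c(0, 0.5),
                          offset_s = c(0.5, 1)),
               data.frame(dimension = "C", main_code = 1, sub_code = 1,
                          onset_s = 0, offset_s = 1))
  tl <- rasterize(ann, fps = 30, duration_s = 1, participant = "infant")
  expect_equal(nFrames(tl), 30)
  expect_equal(mainCodes(tl, "SE"), rep(1L, 30))
  ## frame 15 starts at exactly 0.5 s: boundary belongs to the later interval
  sm <- mainCodes(tl, "SM")
  expect_equal(sm[1:15], rep(1L, 15))
  expect_equal(sm[16:30], rep(0L, 15))
})

test_that("rasterization rejects overlaps and uncovered gaps, honors fill", {
  full <- function(d) data.frame(dimension = d, main_code = 1, sub_code = 1,
                                 onset_s = 0, offset_s = 1)
  overlap <- rbind(full("SM")[0, ],
                   data.frame(dimension = "SE", main_code = c(1, 0),
                              sub_code = c(1, 1), onset_s = c(0, 0.4),
                              offset_s = c(0.6, 1)),
                   full("SM"), full("C"))
  expect_error(rasterize(overlap, fps = 30, duration_s = 1,
                         participant = "infant"),
               "SE: overlapping intervals")

  gap <- rbind(data.frame(dimension = "SE", main_code = 1, sub_code = 1,
                          onset_s = 0.5, offset_s = 1),
               full("SM"), full("C"))
  expect_error(rasterize(gap, fps = 30, duration_s = 1,
                         participant = "infant"),
               "SE: uncovered gap \\[0, 0.5\\)")
  ## with a fill policy the gap takes the configured main code
  tl <- rasterize(gap, fps = 30, duration_s = 1, participant = "infant",
                  fill = c(SE = 0))
  expect_equal(mainCodes(tl, "SE"), rep(c(0L, 1L), each = 15))
})

test_that("rasterize then de-rasterize reproduces frame-aligned partitions exactly", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(50:400, 1)
    ann <- randomAnnotations(n, fps = 30)
    tl <- rasterize(ann, fps = 30, duration_s = n / 30)
    back <- annotationsFromTimeline(tl)
    for (d in c("SE", "SM", "C")) {
      a <- ann[ann$dimension == d, ]
      b <- back[back$dimension == d, ]
      ## adjacent intervals with identical (main, sub) merge; normalize both
      norm <- function(x) {
        key <- paste(x$main_code, x$sub_code)
        r <- rle(key)
        ends <- cumsum(r$lengths)
        starts <- c(1, head(ends, -1) + 1)
        data.frame(main = x$main_code[starts], sub = x$sub_code[starts],
                   on = x$onset_s[starts], off = x$offset_s[ends])
      }
      expect_equal(norm(b), norm(a), ignore_attr = TRUE)
    }
  }
})

test_that("alignDyad truncates to the shared clock and refuses resampling", {
  inf <- makeTimeline(rep(1, 300), rep(1, 300), rep(1, 300))
  ad <- makeTimeline(rep(0, 290), rep(0, 290), rep(1, 290),
                     participant = "adult")
  expect_message(dy <- alignDyad(inf, ad), "truncating infant.*290")
  expect_equal(nFrames(dy), 290)

  same <- alignDyad(makeTimeline(1, 1, 1),
                    makeTimeline(1, 1, 1, participant = "adult"))
  expect_equal(nFrames(same), 1)

  ad25 <- makeTimeline(rep(1, 100), rep(1, 100), rep(1, 100), fps = 25,
                       participant = "adult")
  expect_error(alignDyad(inf, ad25), "fps mismatch")
})

test_that("timeline TSV export has the per-frame layout", {
  tl <- makeTimeline(c(1, 0), c(1, 1), c(0, 1), withSubs = TRUE)
  path <- tempfile(fileext = ".tsv")
  writeTimeline(tl, path)
  df <- read.delim(path)
  expect_equal(names(df), c("frame", "t_onset_s", "SE", "SE_sub", "SM",
                            "SM_sub", "C", "C_sub"))
  expect_equal(df$frame, c(0, 1))
  expect_equal(df$t_onset_s[2], 1 / 30, tolerance = 1e-5)
})

test_that("timeline validity catches illegal frames", {
  expect_error(makeTimeline(c(1, 2), c(0, 0), c(0, 0)), "binary")
  codes <- data.frame(SE = 1, SE_sub = 1, SM = 0, SM_sub = 2, C = 1,
                      C_sub = 1)
  expect_error(CodedTimeline("infant", 30, codes), "illegal SM sub-code")
})
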