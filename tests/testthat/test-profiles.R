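uniformBackground <- function() {
  setNames(c(rep(0.99 / 20, 20), 0.01),
           c(AA20_TEST, "-"))
}

tinyProfileSetup <- function() {
  # three tight positive families and two negative-only singletons
  wins <- c(rep("AAAPAAA", 5), rep("GGGPGGG", 3), rep("WWWPWWW", 2),
            "KKKPKKK", "DDDPDDD")
  keys <- sprintf("t%02d:4", seq_along(wins))
  ws <- new("SiteWindowSet", windows = wins,
            proteinID = sub(":4$", "", keys), position = rep(4L, length(wins)), W = 7L)
  ids <- rep(1:5, c(5, 3, 2, 1, 1))
  cl <- new("SiteClustering", keys = keys, cluster = as.integer(ids),
            merge = matrix(0L, 0L, 2L), height = numeric(0), cutHeight = 1)
  lab <- rep(c("positive", "negative"), c(10, 2))  # families 1-3 positive
  ann <- data.frame(protein_id = sub(":4$", "", keys),
                    position = 4L, residue = "P", label = lab,
                    source = "Literature", confidence = NA_real_,
                    collagen = FALSE, evidence_code = NA_character_,
                    key = keys, stringsAsFactors = FALSE)
  list(ws = ws, cl = cl, ann = ann)
}

test_that("one profile is built per positive cluster, from all members", {
  s <- tinyProfileSetup()
  db <- buildProfiles(s$cl, s$ws, s$ann, uniformBackground())
  expect_equal(profileCount(db), 3L)        # negative-only clusters: none
  expect_setequal(names(db@profiles), c("1", "2", "3"))
  expect_equal(length(db@seedKeys[["1"]]), 5L)
  # argmax residue per column reproduces the seed letters
  p1 <- db@profiles[["1"]]
  argmax <- c(AA20_TEST, "-")[apply(p1, 1L, which.max)]
  expect_equal(paste(argmax, collapse = ""), "AAAPAAA")
  # pseudocount keeps every log-odds finite
  expect_true(all(is.finite(p1)))
  noPos <- s$ann; noPos$label <- "negative"
  expect_error(buildProfiles(s$cl, s$ws, noPos, uniformBackground()),
               "no positive clusters")
})

test_that("gap columns are modelled as a 21st emission symbol", {
  wins <- c(rep("---PAAA", 4), "AAAPAAA")
  keys <- sprintf("g%02d:1", 1:5)
  ws <- new("SiteWindowSet", windows = wins, proteinID = sub(":1$", "", keys),
            position = rep(1L, 5), W = 7L)
  cl <- new("SiteClustering", keys = keys, cluster = rep(1L, 5),
            merge = matrix(0L, 0L, 2L), height = numeric(0), cutHeight = 1)
  ann <- data.frame(protein_id = sub(":1$", "", keys), position = 1L,
                    residue = "P", label = "positive", source = "Literature",
                    confidence = NA_real_, collagen = FALSE,
                    evidence_code = NA_character_, key = keys)
  db <- buildProfiles(cl, ws, ann, uniformBackground())
  p <- db@profiles[[1]]
  # gap is the dominant symbol in the padded columns
  expect_equal(unname(apply(p[1:3, ], 1L, which.max)), rep(21L, 3))
})

test_that("null calibration is reproducible and gates scanning", {
  s <- tinyProfileSetup()
  db <- buildProfiles(s$cl, s$ws, s$ann, uniformBackground())
  expect_false(isCalibrated(db))
  expect_error(scanSites(s$ws, db), "not calibrated")
  db1 <- calibrateNull(db, 5000L, seed = 17L)
  db2 <- calibrateNull(db, 5000L, seed = 17L)
  expect_identical(db1@nullLocation, db2@nullLocation)
  expect_identical(db1@nullScale, db2@nullScale)
  expect_false(identical(calibrateNull(db, 5000L, seed = 18L)@nullLocation,
                         db1@nullLocation))
  expect_warning(calibrateNull(db, 500L, seed = 1L), "unstable")
})

test_that("seed members are recovered and thresholds act monotonically", {
  s <- tinyProfileSetup()
  db <- calibrateNull(buildProfiles(s$cl, s$ws, s$ann, uniformBackground()),
                      5000L, seed = 17L)
  scan <- scanSites(s$ws, db)
  seedKeys <- unlist(db@seedKeys)
  expect_true(all(scan$call[scan$key %in% seedKeys] == 1L))
  # seed members best-hit their own cluster's profile
  expect_equal(scan$bestProfile[match(db@seedKeys[["2"]], scan$key)],
               rep("2", 3))
  # an effectively infinite threshold calls every site positive
  scanAll <- scanSites(s$ws, db, evalueMax = 1e12)
  expect_true(all(scanAll$call == 1L))
  # tightening the threshold only shrinks the positive set
  prev <- rep(TRUE, length(s$ws))
  for (em in c(1, 1e-2, 1e-4, 1e-8)) {
    cur <- scanSites(s$ws, db, evalueMax = em)$call == 1L
    expect_true(all(cur <= prev))
    prev <- cur
  }
  expect_error(scanSites(s$ws, db, evalueMax = 0), "> 0")
})

test_that("seed and background E-values separate by orders of magnitude", {
  s <- tinyProfileSetup()
  db <- calibrateNull(buildProfiles(s$cl, s$ws, s$ann, uniformBackground()),
                      10000L, seed = 19L)
  set.seed(20)
  nullWins <- vapply(1:400, function(i)
    paste(sample(AA20_TEST, 7, replace = TRUE), collapse = ""), character(1))
  ws <- new("SiteWindowSet", windows = nullWins,
            proteinID = sprintf("z%03d", 1:400), position = rep(4L, 400),
            W = 7L)
  nullE <- scanSites(ws, db)$evalue
  seedScan <- scanSites(s$ws, db)
  seedE <- seedScan$evalue[seedScan$key %in% unlist(db@seedKeys)]
  # typical random windows sit near the database-size scale, seeds far in
  # the tail; at a stringent cut essentially no random window is called
  expect_gt(median(nullE), 0.5)
  expect_lt(max(seedE), 1e-3)
  expect_lt(mean(nullE <= 0.01), 0.05)
})

test_that("profile TSV serialization keeps all 21 scores per column", {
  s <- tinyProfileSetup()
  db <- buildProfiles(s$cl, s$ws, s$ann, uniformBackground())
  f <- tempfile(fileext = ".tsv")
  writeProfilesTSV(db, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), 3L * 7L)
  expect_equal(ncol(back), 2L + 21L)
  expect_equal(back[["A"]][1:7], unname(db@profiles[["1"]][, 1]))
})
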