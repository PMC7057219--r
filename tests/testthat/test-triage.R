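rand_stats <- function(i) {
  solution_stats(
    id = paste0("s", i),
    shelxe_cc = runif(1, 5, 60),
    r_free = runif(1, 0.25, 0.6),
    r_gap = runif(1, 0, 0.15),
    side_chains = sample(0:40, 1),
    map_cc = runif(1, 0, 1))
}

status_rank <- function(v) match(v$status, c("reject", "borderline", "accept"))

test_that("worked solution patterns are judged as in practice", {
  # high CC but overfitting gap and no side chains: rejected despite the CC
  bad <- solution_stats("reversed", shelxe_cc = 51.7, r_free = 0.41,
                        r_gap = 0.13, side_chains = 0)
  v <- assess(bad)
  expect_equal(v$status, "reject")
  expect_true(any(grepl("gap", v$reasons)))
  expect_true(any(grepl("side chains", v$reasons)))
  # a sound solution: good CC, R_free, gap, side chains and map agreement
  good <- solution_stats("sound", shelxe_cc = 35, r_free = 0.36, r_gap = 0.03,
                         side_chains = 12, map_cc = 0.77)
  expect_equal(assess(good)$status, "accept")
  # CC below the legacy floor rejects even with good companion statistics
  low <- solution_stats("weak", shelxe_cc = 20, r_free = 0.36, r_gap = 0.03,
                        side_chains = 12)
  vv <- assess(low)
  expect_equal(vv$status, "reject")
  expect_true(any(grepl("legacy floor", vv$reasons)))
})

test_that("unknown auxiliary metrics give borderline, not accept or reject", {
  v <- assess(solution_stats("partial", shelxe_cc = 40, r_free = 0.35))
  expect_equal(v$status, "borderline")
  mid <- assess(solution_stats("midcc", shelxe_cc = 28, r_free = 0.35,
                               r_gap = 0.02, side_chains = 5))
  expect_equal(mid$status, "borderline")
})

test_that("no single passing metric can force acceptance", {
  withr::with_seed(13, {
    for (i in 1:200) {
      s <- rand_stats(i)
      v <- assess(s)
      if (v$status == "accept") {
        expect_gt(s$shelxe_cc, 30)
        expect_lt(s$r_free, 0.45)
        expect_lte(s$r_gap, 0.05)
        expect_gt(s$side_chains, 0)
      }
      # a stellar CC alone cannot rescue a hard failure
      if (s$r_gap > 0.05 || s$side_chains == 0) {
        s2 <- s; s2$shelxe_cc <- 99
        expect_equal(assess(s2)$status, "reject")
      }
    }
  })
})

test_that("improving any one statistic never demotes the verdict", {
  improve <- list(
    function(s) { s$shelxe_cc <- s$shelxe_cc + runif(1, 0, 20); s },
    function(s) { s$r_free <- max(0.01, s$r_free - runif(1, 0, 0.2)); s },
    function(s) { s$r_gap <- max(0, s$r_gap - runif(1, 0, 0.1)); s },
    function(s) { s$side_chains <- s$side_chains + sample(1:10, 1); s },
    function(s) { s$map_cc <- min(1, s$map_cc + runif(1, 0, 0.3)); s })
  withr::with_seed(21, {
    for (i in 1:120) {
      s <- rand_stats(i)
      before <- status_rank(assess(s))
      f <- improve[[sample(length(improve), 1)]]
      expect_gte(status_rank(assess(f(s))), before)
    }
  })
})

test_that("demarcation separates top from background correctly", {
  mk <- function(cc, i) solution_stats(paste0("d", i), cc, r_free = 0.4)
  sols <- Map(mk, c(40, 31, 30, 29), 1:4)
  d <- demarcation(sols)
  expect_equal(d$top$shelxe_cc, 40)
  expect_equal(d$margin, 10)
  expect_true(d$demarcated)
  flat <- Map(mk, rep(33, 4), 1:4)
  df <- demarcation(flat)
  expect_equal(df$margin, 0)
  expect_false(df$demarcated)
  single <- demarcation(list(mk(50, 1)))
  expect_true(is.na(single$demarcated))
  expect_error(demarcation(list()), "no solutions")
})

test_that("ranking is by descending CC and stable for ties", {
  mk <- function(cc, i) solution_stats(paste0("r", i), cc, r_free = 0.4)
  sols <- Map(mk, c(10, 30, 20, 30), 1:4)
  ranked <- rank_solutions(sols)
  expect_equal(vapply(ranked, `[[`, numeric(1), "shelxe_cc"), c(30, 30, 20, 10))
  expect_equal(vapply(ranked, `[[`, character(1), "id")[1:2], c("r2", "r4"))
  # permutation invariance
  ranked2 <- rank_solutions(rev(sols))
  expect_equal(vapply(ranked2, `[[`, numeric(1), "shelxe_cc"),
               c(30, 30, 20, 10))
})

test_that("table triage is consistent with per-solution assessment", {
  mk <- function(id, cc, gap, sc) solution_stats(id, cc, r_free = 0.36,
                                                 r_gap = gap, side_chains = sc)
  sols <- list(mk("top", 45, 0.02, 9), mk("bg1", 22, 0.02, 4),
               mk("bg2", 20, 0.08, 0), mk("bg3", 18, 0.02, 2))
  tb <- triage_solutions(sols)
  expect_equal(tb$id[1], "top")
  expect_equal(tb$status[1], "accept")
  expect_true(all(tb$status[-1] == "reject"))
  # an undemarcated top is demoted to borderline
  close_field <- list(mk("a", 36, 0.02, 9), mk("b", 35, 0.02, 9),
                      mk("c", 34, 0.02, 9))
  tb2 <- triage_solutions(close_field)
  expect_equal(tb2$status[1], "borderline")
  expect_true(any(grepl("demarcation", tb2$reasons[1])))
})

test_that("solution tables read from TSV and CSV", {
  df <- data.frame(id = c("a", "b"), shelxe_cc = c(40, 20),
                   r_free = c(0.35, 0.5), r_gap = c(0.02, 0.1),
                   side_chains = c(8, 0))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  sols <- read_solution_stats(tsv)
  expect_length(sols, 2)
  expect_equal(sols[[1]]$shelxe_cc, 40)
  expect_true(is.na(sols[[1]]$map_cc))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE, quote = FALSE)
  expect_equal(read_solution_stats(csv)[[2]]$r_gap, 0.1)
  bad <- withr::local_tempfile(lines = "id\tcc\n1\t2")
  expect_error(read_solution_stats(bad), "mandatory")
})
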