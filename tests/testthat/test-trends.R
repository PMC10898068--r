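# Randomized record tables built directly (not via extraction), so the
# counting oracles are independent of the pipeline.
random_records_df <- function(n) {
  years <- sample(c(1990:2021, NA), n, replace = TRUE)
  counts <- sample(c(1:12, 25L, 150L, NA), n, replace = TRUE)
  streams <- sample(c("confirmed", "provisional"), n, replace = TRUE,
                    prob = c(0.8, 0.2))
  org <- lapply(seq_len(n), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return(data.frame(species = character(), year = integer()))
    data.frame(species = sample(c("mouse", "zebrafish", "worm", "rat"), k),
               year = sample(c(2005:2022, NA), k, replace = TRUE))
  })
  df <- data.frame(gene_mim = 600000L + seq_len(n),
                   phenotype_mim = 650000L + seq_len(n),
                   gene_symbol = "G", stream = streams,
                   discovery_year = years,
                   discovery_pmid = 70000000L + seq_len(n),
                   discovery_tier = "same_sentence",
                   cohort_count = counts, cohort_unrelated = NA,
                   cohort_same_study = NA, organisms = "",
                   stringsAsFactors = FALSE)
  df$organism_table <- org
  df
}

test_that("yearly counts match a brute-force tally on randomized records", {
  set.seed(31)
  for (trial in 1:200) {
    df <- random_records_df(sample(5:60, 1))
    for (stream in c("both", "confirmed", "provisional")) {
      tt <- yearly_counts(df, stream)
      sub <- if (stream == "both") df else df[df$stream == stream, ]
      for (j in seq_len(nrow(tt)))
        expect_identical(tt$n[j], sum(sub$discovery_year == tt$year[j],
                                      na.rm = TRUE))
      expect_identical(sum(tt$n) + attr(tt, "n_year_unknown"), nrow(sub))
    }
  }
})

test_that("confirmed and provisional yearly counts sum to the both-streams table", {
  set.seed(32)
  df <- random_records_df(200)
  both <- yearly_counts(df, "both")
  conf <- yearly_counts(df, "confirmed")
  prov <- yearly_counts(df, "provisional")
  add <- function(tab, y) if (y %in% tab$year) tab$n[tab$year == y] else 0L
  for (j in seq_len(nrow(both)))
    expect_identical(both$n[j],
                     add(conf, both$year[j]) + add(prov, both$year[j]))
})

test_that("worked example of the bin layout: counts 1,2,3,7 over breaks 1,5,10", {
  df <- random_records_df(4)
  df$cohort_count <- c(1L, 2L, 3L, 7L)
  h <- cohort_size_distribution(df, breaks = c(1L, 5L, 10L))
  expect_identical(h$bin, c("1", "2-5", "6-10"))
  expect_identical(h$n, c(1L, 2L, 1L))
})

test_that("cohort bins match brute-force binning on randomized counts", {
  set.seed(33)
  breaks <- c(1L, 5L, 10L, 100L)
  for (trial in 1:200) {
    df <- random_records_df(sample(5:60, 1))
    h <- cohort_size_distribution(df, breaks)
    cnt <- df$cohort_count[!is.na(df$cohort_count)]
    brute <- function(lo, hi) sum(cnt >= lo & cnt <= hi)
    want <- c("1" = brute(1, 1), "2-5" = brute(2, 5), "6-10" = brute(6, 10),
              "11-100" = brute(11, 100), ">100" = brute(101, .Machine$integer.max))
    want <- want[want > 0]
    expect_identical(stats::setNames(h$n, h$bin), want)
    expect_identical(attr(h, "n_missing"), sum(is.na(df$cohort_count)))
    if (length(cnt))
      expect_equal(attr(h, "share_lt5"), mean(cnt < 5))
  }
})

test_that("all-missing cohort counts produce an empty histogram with n_missing", {
  df <- random_records_df(5)
  df$cohort_count <- NA_integer_
  h <- cohort_size_distribution(df)
  expect_identical(nrow(h), 0L)
  expect_identical(attr(h, "n_missing"), 5L)
})

test_that("organism shares equal brute-force recomputation within the window", {
  set.seed(34)
  for (trial in 1:200) {
    df <- random_records_df(sample(5:50, 1))
    win <- sort(sample(2005:2022, 2))
    sh <- organism_share(df, win)
    pool <- character()
    for (tb in df$organism_table) {
      ok <- !is.na(tb$year) & tb$year >= win[1] & tb$year <= win[2]
      pool <- c(pool, tb$species[ok])
    }
    if (!length(pool)) {
      expect_identical(nrow(sh), 0L)
    } else {
      expect_identical(sum(sh$n), length(pool))
      for (j in seq_len(nrow(sh))) {
        expect_identical(sh$n[j], sum(pool == sh$species[j]))
        expect_equal(sh$share[j], sum(pool == sh$species[j]) / length(pool))
      }
    }
  }
})

test_that("shares reflect a simple known organism mix", {
  df <- random_records_df(4)
  df$organism_table <- list(
    data.frame(species = "mouse", year = 2015L),
    data.frame(species = "mouse", year = 2016L),
    data.frame(species = c("mouse", "zebrafish"), year = c(2017L, 2018L)),
    data.frame(species = character(), year = integer()))
  sh <- organism_share(df, c(2011L, 2021L))
  expect_identical(sh$species, c("mouse", "zebrafish"))
  expect_equal(sh$share, c(0.75, 0.25))
})

test_that("benchmark comparison arithmetic matches a brute-force recount", {
  set.seed(35)
  for (trial in 1:200) {
    df <- random_records_df(sample(8:40, 1))
    n <- nrow(df)
    in_bm <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.7, 0.3))
    bm <- df[in_bm, c("gene_mim", "phenotype_mim")]
    conflict <- stats::runif(nrow(bm)) < 0.25
    bm$pmid <- ifelse(conflict, 1L, df$discovery_pmid[in_bm])
    rep <- compare_to_benchmark(df, bm)
    expect_identical(rep$n_compared, nrow(bm))
    expect_identical(rep$n_matched, sum(!conflict))
    expect_identical(rep$n_conflicting, sum(conflict))
    expect_identical(rep$n_absent_in_benchmark, sum(!in_bm))
    expect_identical(rep$n_matched + rep$n_conflicting, rep$n_compared)
    if (nrow(bm))
      expect_equal(rep$match_share, sum(!conflict) / nrow(bm))
    expect_identical(nrow(rep$conflicts), sum(conflict))
  }
})

test_that("identical tables match perfectly and duplicate keys error", {
  df <- random_records_df(10)
  bm <- df[, c("gene_mim", "phenotype_mim")]
  bm$pmid <- df$discovery_pmid
  rep <- compare_to_benchmark(df, bm)
  expect_equal(rep$match_share, 1)
  expect_identical(rep$n_conflicting, 0L)
  expect_error(compare_to_benchmark(df, rbind(bm, bm[1, ])), "duplicate")
  # 12 of 13 equal
  df13 <- random_records_df(13)
  bm13 <- df13[, c("gene_mim", "phenotype_mim")]
  bm13$pmid <- df13$discovery_pmid
  bm13$pmid[5] <- 999L
  rep13 <- compare_to_benchmark(df13, bm13)
  expect_identical(rep13$n_matched, 12L)
  expect_identical(rep13$n_conflicting, 1L)
})

test_that("benchmark CSV round-trips through the reader", {
  f <- withr::local_tempfile(fileext = ".csv")
  bm <- data.frame(gene_mim = 600001L, phenotype_mim = 650001L,
                   pmid = 70000001L)
  utils::write.csv(bm, f, row.names = FALSE)
  expect_identical(read_benchmark_csv(f), bm)
})
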