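test_that("built-in collapsing matrices match the published models cell for cell", {
  strip <- function(M) matrix(as.integer(M), 4, 4)
  M <- collapsing_matrix("recessive-default")
  expect_identical(strip(M),
                   matrix(as.integer(c(0, 0, 0, 0,
                                       0, 1, 1, 1,
                                       0, 1, 0, 3,
                                       0, 1, 3, 3)), 4, byrow = TRUE))
  A <- collapsing_matrix("additive-alternative")
  expect_identical(strip(A),
                   matrix(as.integer(c(0, 0, 0, 0,
                                       0, 1, 1, 1,
                                       0, 1, 0, 2,
                                       0, 1, 2, 3)), 4, byrow = TRUE))
  # both-het collapses to carrier; het + hom-major to non-carrier (default)
  expect_identical(collapse_codes(2, 2, M), 0L)
  expect_identical(collapse_codes(2, 3, M), 3L)
  # additive model grades het + hom-major as the intermediate pseudo-code
  expect_identical(collapse_codes(2, 3, A), 2L)
  # missing partner: hom-minor dominates, anything else is missing
  expect_identical(collapse_codes(0, 1, M), 0L)
  expect_identical(collapse_codes(1, 2, M), 1L)
})

test_that("invalid custom matrices are rejected with the offending cell", {
  bad <- matrix(0L, 4, 4); bad[2, 3] <- 4L
  expect_error(collapsing_matrix(bad), "\\[2, 3\\] is 4")
  expect_error(collapsing_matrix(matrix(0L, 3, 3)), "4x4")
  expect_error(collapsing_matrix("no-such-model"), "unknown collapsing model")
})

test_that("collapsing matrices load from 4x4 text files", {
  path <- tempfile()
  writeLines(c("0 0 0 0", "0 1 1 1", "0 1 0 3", "0 1 3 3"), path)
  M <- collapsing_matrix(path)
  expect_identical(matrix(as.integer(M), 4, 4),
                   matrix(as.integer(collapsing_matrix("recessive-default")), 4, 4))
})

test_that("byte lookup table equals per-genotype collapsing on all 65536 byte pairs", {
  M <- collapsing_matrix("recessive-default")
  tab <- build_byte_table(M)
  # row of all hom-minor collapses every partner byte to carrier bytes
  expect_true(all(tab[0x00 + 1L, ] == as.raw(0x00)))
  # hom-major with hom-major stays hom-major at all four positions
  expect_identical(tab[0xFF + 1L, 0xFF + 1L], as.raw(0xFF))

  # exhaustive equivalence, position by position
  for (pos in 1:4) {
    shift <- 2L * (pos - 1L)
    a_codes <- bitwAnd(bitwShiftR(rep(0:255, times = 256), shift), 3L)
    b_codes <- bitwAnd(bitwShiftR(rep(0:255, each = 256), shift), 3L)
    got <- bitwAnd(bitwShiftR(as.integer(tab), shift), 3L)
    want <- oracle_collapse(a_codes, b_codes, M)
    expect_identical(got, want)
  }
})

test_that("genome shifting pairs variants within chromosomes only", {
  d <- rand_dataset(5, 6, missing_rate = 0, seed = 3)
  s1 <- shift_genome(d, 1)
  expect_identical(s1$m, 4L)
  expect_identical(s1$pairs$left_index, 1:4)
  expect_identical(s1$pairs$right_index, 2:5)
  expect_identical(s1$variants$id, paste0(d$variants$id[1:4], "/",
                                          d$variants$id[2:5]))
  expect_identical(s1$variants$bp, d$variants$bp[1:4])

  d2 <- rand_dataset(c(3, 2), 6, seed = 4)
  s2 <- shift_genome(d2, 2)
  expect_identical(s2$m, 1L)
  expect_identical(s2$pairs$chr, "chr1")

  expect_warning(s5 <- shift_genome(d2, 5), "empty shifted")
  expect_identical(s5$m, 0L)
})

test_that("shifted pseudo-genotypes equal the per-genotype oracle", {
  d <- rand_dataset(40, 11, missing_rate = 0.1, seed = 5)
  G <- genotype_matrix(d)
  for (M in list(collapsing_matrix("recessive-default"),
                 collapsing_matrix("additive-alternative"))) {
    s <- shift_genome(d, 3, M)
    want <- t(vapply(seq_len(s$m), function(t) {
      oracle_collapse(G[s$pairs$left_index[t], ], G[s$pairs$right_index[t], ],
                      M)
    }, integer(d$n)))
    expect_identical(genotype_matrix(s), want)
  }
})

test_that("pad bits stay zero even when the matrix maps (0,0) to a nonzero code", {
  M <- collapsing_matrix(matrix(3L, 4, 4))  # every cell, incl. [0,0], -> 3
  d <- rand_dataset(6, 5, missing_rate = 0, seed = 6)  # ragged final byte
  s <- shift_genome(d, 1, M)
  # n = 5: the final byte of each pseudo-variant holds sample 5 in its low bit
  # pair; the upper 6 pad bits must be zero, so the byte value is < 4
  last <- as.integer(s$bed[nrow(s$bed), ])
  expect_true(all(last < 4L))
  # and every real genotype collapsed to code 3 as the matrix dictates
  expect_true(all(genotype_matrix(s) == 3L))
})

test_that("window enumeration counts and set identity hold", {
  d <- rand_dataset(5, 4, seed = 7)
  wp <- window_pairs(d, 2)
  expect_identical(nrow(wp), 7L)  # m*k - k(k+1)/2 = 10 - 3
  expect_setequal(paste(wp$left_index, wp$right_index),
                  c("1 2", "2 3", "3 4", "4 5", "1 3", "2 4", "3 5"))
  # window truncated at chromosome end
  d3 <- rand_dataset(3, 4, seed = 8)
  expect_identical(nrow(window_pairs(d3, 5)), 3L)
})

test_that("genome shifting over 1..k equals the sliding-window enumeration", {
  # multiset identity of (pair, collapsed vector) across random layouts
  M <- collapsing_matrix()
  for (seed in 1:6) {
    set.seed(seed)
    sizes <- sample(2:25, sample(1:3, 1))
    k <- sample(1:6, 1)
    d <- rand_dataset(sizes, 9, missing_rate = 0.1)
    G <- genotype_matrix(d)
    wp <- window_pairs(d, k)
    direct <- lapply(seq_len(nrow(wp)), function(r) {
      list(key = paste(wp$left_index[r], wp$right_index[r]),
           g = oracle_collapse(G[wp$left_index[r], ], G[wp$right_index[r], ], M))
    })
    shifted <- list()
    for (i in seq_len(k)) {
      s <- suppressWarnings(shift_genome(d, i, M))
      if (s$m == 0) next
      Gs <- genotype_matrix(s)
      for (t in seq_len(s$m)) {
        shifted[[length(shifted) + 1L]] <-
          list(key = paste(s$pairs$left_index[t], s$pairs$right_index[t]),
               g = Gs[t, ])
      }
    }
    expect_identical(length(shifted), nrow(wp))
    okey <- order(vapply(direct, `[[`, "", "key"))
    skey <- order(vapply(shifted, `[[`, "", "key"))
    expect_identical(lapply(shifted[skey], identity),
                     lapply(direct[okey], identity))
  }
})

test_that("symmetric matrices make collapsing order-independent", {
  M <- collapsing_matrix()
  g <- expand.grid(0:3, 0:3)
  expect_identical(collapse_codes(g[, 1], g[, 2], M),
                   collapse_codes(g[, 2], g[, 1], M))
})
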