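test_that("profile of a single-row MSA is the query one-hot", {
  p <- build_profile("ACDY")
  expect_equal(dim(p), c(4L, 21L))
  expect_equal(rowSums(p), rep(1, 4))
  expect_equal(unname(p[1, "A"]), 1)
  expect_equal(unname(p[2, "C"]), 1)
  expect_equal(unname(p[4, "Y"]), 1)
})

test_that("profile counts amino-acid and gap frequencies per column", {
  msa <- c("AG", "AG", "GG", "-G")
  p <- build_profile(msa)
  expect_equal(unname(p[1, "A"]), 0.5)
  expect_equal(unname(p[1, "G"]), 0.25)
  expect_equal(unname(p[1, "gap"]), 0.25)
  expect_equal(unname(p[2, "G"]), 1)
})

test_that("profile matches an independent per-column tally on random MSAs", {
  set.seed(11)
  aa <- c(disbrnn:::AA20, "-")
  msa <- vapply(1:10, function(i)
    paste(sample(aa, 30, replace = TRUE, prob = c(rep(1, 20), 2)),
          collapse = ""), "")
  # query row must be ungapped for coordinates to be trivial here
  msa[1] <- paste(sample(disbrnn:::AA20, 30, replace = TRUE), collapse = "")
  p <- build_profile(msa)
  m <- do.call(rbind, strsplit(msa, ""))
  for (j in seq_len(30)) {
    for (k in seq_len(20))
      expect_identical(unname(p[j, k]), mean(m[, j] == disbrnn:::AA20[k]))
    expect_identical(unname(p[j, 21]), mean(m[, j] == "-"))
  }
})

test_that("query-gap columns are dropped; nonstandard letters spread out", {
  msa <- c("A-C", "GYC")
  p <- build_profile(msa)
  expect_equal(nrow(p), 2L)               # middle column dropped
  expect_equal(unname(p[1, "A"]), 0.5)
  expect_equal(unname(p[1, "G"]), 0.5)

  px <- build_profile(c("AC", "XC"))
  expect_equal(unname(px[1, "A"]), 0.5 + 0.5 / 20)
  expect_equal(unname(px[1, "W"]), 0.5 / 20)
  expect_equal(sum(px[1, ]), 1)

  expect_error(build_profile(c("AC", "A")), "unequal")
})

test_that("secondary-structure and accessibility one-hots are exact", {
  expect_equal(unname(encode_ss("HEC")), diag(3))
  expect_equal(unname(encode_ss("CCCCC")),
               matrix(rep(c(0, 0, 1), each = 5), 5, 3))
  expect_equal(unname(encode_sa("BbeE")), diag(4))
  expect_equal(unname(encode_sa("EE")),
               matrix(c(0, 0, 0, 0, 0, 0, 1, 1), 2, 4))
  expect_error(encode_ss("HXC"), "invalid")
  expect_error(encode_sa("BqE"), "invalid")
})

test_that("one-hot encodings round-trip through argmax decoding", {
  set.seed(12)
  ss <- paste(sample(c("H", "E", "C"), 50, replace = TRUE), collapse = "")
  dec <- c("H", "E", "C")[apply(encode_ss(ss), 1, which.max)]
  expect_identical(paste(dec, collapse = ""), ss)
  sa <- paste(sample(c("B", "b", "e", "E"), 50, replace = TRUE),
              collapse = "")
  dec2 <- c("B", "b", "e", "E")[apply(encode_sa(sa), 1, which.max)]
  expect_identical(paste(dec2, collapse = ""), sa)
})

test_that("template encoding handles absence, single and multiple hits", {
  expect_equal(encode_templates(list(), 4),
               matrix(0, 4, 3, dimnames = list(NULL, c("ordered",
                                                       "disordered",
                                                       "score"))))
  one <- template_hit("t1", 1.0, "DD")
  enc1 <- encode_templates(list(one), 2)
  expect_equal(unname(enc1[1, ]), c(0, 1, 1))

  # two covering hits: weights 0.9^3 and 0.2^3
  hits <- list(template_hit("t1", 0.9, "O"), template_hit("t2", 0.2, "D"))
  enc <- encode_templates(hits, 1)
  expect_equal(unname(enc[1, 1]), 0.98915, tolerance = 1e-5 / 0.98915)
  expect_equal(unname(enc[1, 2]), 0.01085, tolerance = 1e-5 / 0.01085)
  expect_equal(unname(enc[1, 3]), 0.89240, tolerance = 1e-5 / 0.89240)

  # uncovered positions stay blank
  frag <- template_hit("t3", 0.8, "O-D")
  encf <- encode_templates(list(frag), 3)
  expect_equal(unname(encf[2, ]), c(0, 0, 0))
  expect_equal(unname(encf[1, ]), c(1, 0, 0.8))

  expect_error(encode_templates(list(template_hit("t", 0.5, "OD")), 3),
               "length")
})

test_that("template-encoding algebra: normalization, score bounds, dominance", {
  set.seed(13)
  n <- 40
  for (rep in 1:10) {
    hits <- lapply(1:3, function(i) {
      ann <- sample(c("O", "D", "-"), n, replace = TRUE)
      template_hit(paste0("t", i), runif(1, 0.05, 0.95),
                   paste(ann, collapse = ""))
    })
    enc <- encode_templates(hits, n)
    idm <- vapply(hits, `[[`, numeric(1), "identity")
    annm <- do.call(rbind, lapply(hits, function(h)
      strsplit(h$annotation, "")[[1]]))
    for (j in seq_len(n)) {
      cov <- annm[, j] != "-"
      if (!any(cov)) {
        expect_equal(unname(enc[j, ]), c(0, 0, 0))
      } else {
        expect_equal(unname(enc[j, 1] + enc[j, 2]), 1)
        expect_gte(unname(enc[j, 3]), min(idm[cov]) - 1e-12)
        expect_lte(unname(enc[j, 3]), max(idm[cov]) + 1e-12)
        if (sum(cov) == 1) expect_equal(unname(enc[j, 3]), unname(idm[cov]))
      }
    }
  }
  # raising a hit's identity strictly increases its label's component
  h1 <- template_hit("a", 0.5, "O"); h2 <- template_hit("b", 0.6, "D")
  base <- encode_templates(list(h1, h2), 1)[1, 1]
  up <- encode_templates(list(template_hit("a", 0.7, "O"), h2), 1)[1, 1]
  expect_gt(up, base)
})

test_that("identity filtering retains hits at or below the cap", {
  mk <- function(i) template_hit(paste0("t", i * 100), i, "O")
  hits <- lapply(c(0.99, 0.95, 0.40), mk)
  kept <- filter_hits_by_identity(hits)
  expect_equal(vapply(kept, `[[`, numeric(1), "identity"), c(0.95, 0.40))
  expect_identical(filter_hits_by_identity(list()), list())
  kept50 <- filter_hits_by_identity(lapply(c(0.6, 0.5, 0.2), mk), 0.50)
  expect_equal(vapply(kept50, `[[`, numeric(1), "identity"), c(0.5, 0.2))
})

test_that("assembled input widths match the four system variants", {
  rec <- tiny_corpus(1, seed = 31)[[1]]
  n <- nchar(rec$sequence)
  for (v in c("MSA", "MSA-SS-SA", "MSA-Templ", "MSA-SS-SA-Templ")) {
    X <- assemble_inputs(v, rec)
    expect_equal(dim(X), c(n, variant_width(v)))
    expect_true(all(is.finite(X)))
  }
  expect_identical(variant_width("MSA"), 21L)
  expect_identical(variant_width("MSA-SS-SA"), 28L)
  expect_identical(variant_width("MSA-Templ"), 24L)
  expect_identical(variant_width("MSA-SS-SA-Templ"), 31L)

  # zero hits: template block present but blank
  rec$template_hits <- list()
  Xt <- assemble_inputs("MSA-Templ", rec)
  expect_equal(ncol(Xt), 24L)
  expect_true(all(Xt[, 22:24] == 0))

  rec$msa <- NULL
  expect_error(assemble_inputs("MSA", rec), "msa")
  rec2 <- tiny_corpus(1, seed = 32)[[1]]
  rec2$ss <- NULL
  expect_error(assemble_inputs("MSA-SS-SA", rec2), "ss")
})
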