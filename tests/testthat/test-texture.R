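test_that("quantization bins the mask-true range into equal-width levels", {
  m <- matrix(c(0, 1, 2, 3), 2, 2)
  q <- quantize(m, Ng = 4L)
  expect_identical(sort(as.vector(q$levels)), 1:4)

  q2 <- quantize(matrix(c(0, 10, 0, 10), 2, 2), Ng = 128L)
  expect_identical(sort(unique(as.vector(q2$levels))), c(1L, 128L))

  # constant region maps to level 1
  qc <- quantize(matrix(5, 3, 3), Ng = 128L)
  expect_true(all(qc$levels == 1L))

  # masked-out pixels receive no level
  msk <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  q3 <- quantize(m, msk, Ng = 4L)
  expect_true(is.na(q3$levels[!msk]))
  expect_error(quantize(m, matrix(FALSE, 2, 2)), "empty mask")
})

test_that("symmetric GLCM counts pairs and their reverses, normalized", {
  g <- compute_glcm(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE),
                    distance = 1L, angle = 0L, Ng = 2L)
  expect_equal(g$p, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))

  gk <- compute_glcm(matrix(3L, 3, 3), distance = 1L, angle = 45L, Ng = 4L)
  expect_equal(gk$p[3, 3], 1)
  expect_equal(sum(gk$p), 1)

  # any window matches an independent offset-shift oracle, all angles
  set.seed(31)
  for (rep in 1:10) {
    w <- matrix(sample.int(6L, 25L, replace = TRUE), 5, 5)
    for (a in c(0L, 45L, 90L, 135L)) {
      g <- compute_glcm(w, 1L, a, Ng = 6L)
      expect_equal(g$p, oracle_glcm(w, 1L, a, 6L))
      expect_equal(sum(g$p), 1, tolerance = 1e-12)
      expect_equal(g$p, t(g$p))
    }
  }

  expect_error(compute_glcm(matrix(1L, 1, 1), 2L, 0L), "no valid")
})

test_that("texture features match hand-evaluated formulas", {
  # point mass: degenerate single-outcome convention
  p <- matrix(0, 5, 5); p[3, 3] <- 1
  f <- texture_features(p)
  expect_equal(unname(f),
               c(0, 0, 1, 1, 3, 1, 0, 1),
               tolerance = 1e-12)

  # hand-evaluated two-level GLCM
  p2 <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  f2 <- texture_features(p2)
  expect_equal(f2[["ENT"]], 1.5)
  expect_equal(f2[["CON"]], 0.5)
  expect_equal(f2[["ENE"]], 0.375)
  expect_equal(f2[["MAX"]], 0.5)
  expect_equal(f2[["MEA"]], 1.25)
  expect_equal(f2[["STD"]], sqrt(0.1875))
  expect_equal(f2[["HOM"]], 0.75)
  expect_equal(f2[["COR"]], -1 / 3)

  # uniform GLCM closed forms
  Ng <- 8L
  pu <- matrix(1 / Ng^2, Ng, Ng)
  fu <- texture_features(pu)
  expect_equal(fu[["ENT"]], 2 * log2(Ng))
  expect_equal(fu[["ENE"]], 1 / Ng^2)
  expect_equal(fu[["MAX"]], 1 / Ng^2)

  expect_error(texture_features(matrix(0.3, 2, 2)), "not normalized")
})

test_that("texture feature ranges hold on random GLCMs", {
  set.seed(7)
  for (rep in 1:20) {
    w <- matrix(sample.int(8L, 36L, replace = TRUE), 6, 6)
    f <- texture_features(compute_glcm(w, 1L, sample(c(0L, 45L, 90L, 135L), 1L),
                                       Ng = 8L))
    expect_gt(f[["ENE"]], 0); expect_lte(f[["ENE"]], 1)
    expect_gt(f[["MAX"]], 0); expect_lte(f[["MAX"]], 1)
    expect_gt(f[["HOM"]], 0); expect_lte(f[["HOM"]], 1)
    expect_gte(f[["CON"]], 0)
    expect_gte(f[["STD"]], 0)
    expect_gte(f[["ENT"]], 0)
    expect_gte(f[["COR"]], -1); expect_lte(f[["COR"]], 1)
  }
})

test_that("parametric maps equal the naive per-pixel oracle", {
  # ragged-mask random slices, mostly at coarse quantization plus two at 128
  for (s in 1:5) {
    q <- random_quantized_slice(16L, Ng = if (s <= 3) 16L else 128L, seed = s)
    pm <- parametric_maps(q)
    or <- oracle_maps(q)
    expect_identical(pm$validity, or$validity)
    for (m in names(or$maps))
      expect_equal(pm$maps[[m]], or$maps[[m]], tolerance = 1e-10)
  }
})

test_that("parametric map geometry and degenerate inputs behave", {
  # constant slice: translation invariance makes every map constant
  q <- quantize(matrix(7, 8, 8), Ng = 128L)
  pm <- parametric_maps(q)
  v <- pm$validity
  expect_equal(unique(pm$maps$ENT[v]), 0)
  expect_equal(unique(pm$maps$HOM[v]), 1)
  expect_equal(unique(pm$maps$ENE[v]), 1)
  expect_equal(unique(pm$maps$COR[v]), 1)
  expect_equal(unique(pm$maps$CON[v]), 0)

  # 3x3 ROI: exactly one valid center
  msk <- matrix(FALSE, 7, 7); msk[3:5, 3:5] <- TRUE
  q2 <- quantize(matrix(rnorm(49), 7, 7), msk, 16L)
  pm2 <- parametric_maps(q2)
  expect_equal(pm2$n_valid, 1L)
  expect_true(pm2$validity[4, 4])

  # ROI too small for any window
  msk3 <- matrix(FALSE, 7, 7); msk3[3:4, 3:5] <- TRUE
  q3 <- quantize(matrix(rnorm(49), 7, 7), msk3, 16L)
  expect_error(parametric_maps(q3), "too small")
})

test_that("SDT features carry map-feature names and constant propagation", {
  q <- quantize(matrix(4.2, 12, 12), Ng = 128L)
  v <- sdt_features(parametric_maps(q))
  expect_length(v, 72L)
  expect_identical(names(v), feature_names("hybrid"))
  sdt <- v[feature_names("sdt")]
  expect_length(sdt, 64L)
  expect_true("ENT_CON" %in% names(sdt))
  # constant first-pass maps: second-pass entropy 0, energy 1 everywhere
  tex <- feature_names("textural")
  expect_equal(unname(sdt[paste0(tex, "_ENT")]), rep(0, 8))
  expect_equal(unname(sdt[paste0(tex, "_ENE")]), rep(1, 8))
})

test_that("tumor aggregation is the ROI-area-weighted mean", {
  v1 <- c(A = 1); v2 <- c(A = 3)
  expect_equal(unname(aggregate_tumor(list(v1, v2), c(10, 30))), 2.5)
  expect_equal(unname(aggregate_tumor(list(v1, v2), c(5, 5))), 2)
  expect_equal(unname(aggregate_tumor(list(v2), 17)), 3)
  expect_error(aggregate_tumor(list(), numeric(0)), "nothing to aggregate")
})

test_that("full extraction yields 72 finite features, invariant to shift and slice order", {
  co <- shared_cohort()
  img <- co$images[[1]]
  v <- extract_features(img)
  expect_length(v, 72L)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), feature_names("hybrid"))

  # determinism
  expect_identical(v, extract_features(img))

  # additive intensity shift: quantization is range-relative
  img_shift <- img
  img_shift$volume <- img$volume + 250
  expect_equal(extract_features(img_shift), v, tolerance = 1e-9)

  # slice order relabeling
  perm <- rev(seq_len(dim(img$volume)[1]))
  img_perm <- img
  img_perm$volume <- img$volume[perm, , , drop = FALSE]
  img_perm$mask <- img$mask[perm, , , drop = FALSE]
  expect_equal(extract_features(img_perm), v, tolerance = 1e-12)
})

test_that("contrast separates classes in the direction of the correlation lengths", {
  # shorter correlation length (NR default) => higher contrast
  tab <- shared_features()
  conR <- tab$CON[tab$label == "R"]
  conNR <- tab$CON[tab$label == "NR"]
  expect_gt(mean(conNR), mean(conR))
  expect_lt(feature_ttest(tab, "CON")$p, 0.05)
})

test_that("feature tables round-trip through CSV", {
  tab <- shared_features()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  fc <- feature_names("hybrid")
  expect_equal(back[fc], tab[fc], tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$label, tab$label)
})
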