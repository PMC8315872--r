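test_that("confusion counts agree with an exhaustive voxel loop", {
  set.seed(1)
  for (i in 1:3) {
    p <- random_mask(c(8L, 8L, 8L))
    t_ <- random_mask(c(8L, 8L, 8L))
    cc <- confusion_counts(p, t_)
    oc <- oracle_confusion(p, t_)
    expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")], oc)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 512)
  }
  m <- random_mask()
  inv <- binary_mask(!m$data)
  cc <- confusion_counts(m, inv)
  expect_equal(cc$tp, 0)
  expect_equal(cc$tn, 0)
  expect_error(confusion_counts(m, random_mask(c(4L, 4L, 4L))), "same grid")
})

test_that("Dice follows its closed form", {
  mk <- function(tp, fp, fn, tn) structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_counts")
  expect_equal(dice(mk(10, 0, 0, 5)), 1)
  expect_equal(dice(mk(0, 4, 6, 5)), 0)
  expect_equal(dice(mk(2, 2, 2, 0)), 0.5)
  expect_error(dice(mk(0, 0, 0, 10)), "empty")
})

test_that("MCC follows the Matthews definition with the zero-marginal flag", {
  mk <- function(tp, fp, fn, tn) structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_counts")
  expect_equal(mcc(mk(8, 0, 0, 8)), 1)
  expect_equal(mcc(mk(0, 8, 8, 0)), -1)
  expect_equal(mcc(mk(2, 1, 1, 4)), 7 / 15)
  z <- mcc(mk(5, 3, 0, 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("FPR/FNR and TP%/FP% are normalized by the reference size", {
  mk <- function(tp, fp, fn, tn) structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_counts")
  expect_equal(fpr_fnr(mk(10, 0, 0, 5)), list(fpr = 0, fnr = 0))
  expect_equal(fpr_fnr(mk(8, 2, 2, 5)), list(fpr = 0.2, fnr = 0.2))
  expect_equal(fpr_fnr(mk(20, 5, 0, 0))$fpr, 0.25)  # pure oversegmentation
  expect_equal(tp_fp_percent(mk(90, 5, 10, 0)),
               list(tp_pct = 90, fp_pct = 5))
  expect_equal(tp_fp_percent(mk(5, 0, 5, 0)), list(tp_pct = 50, fp_pct = 0))
  expect_error(fpr_fnr(mk(0, 3, 0, 7)), "empty reference")
})

test_that("surface extraction matches the 6-neighbor definition", {
  d <- c(7L, 7L, 7L)
  single <- array(FALSE, dim = d)
  single[4, 4, 4] <- TRUE
  s <- extract_surface(binary_mask(single, spacing = c(0.5, 0.5, 0.5)))
  expect_equal(nrow(s), 1L)
  expect_equal(as.numeric(s), c(3, 3, 3) * 0.5)

  cube <- array(FALSE, dim = d)
  cube[3:5, 3:5, 3:5] <- TRUE
  expect_equal(nrow(extract_surface(binary_mask(cube))), 26L)

  full <- binary_mask(array(TRUE, dim = d))
  expect_equal(nrow(extract_surface(full)), 7^3 - 5^3)

  set.seed(2)
  m <- random_blob_mask()
  expect_equal(nrow(extract_surface(m)), oracle_surface_count(m))
  expect_error(extract_surface(binary_mask(array(FALSE, dim = d))), "empty")
})

test_that("surface distances match brute-force double loops", {
  expect_equal(amed(rbind(c(0, 0, 0)), rbind(c(3, 0, 0))), 3)
  expect_equal(hausdorff(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(0, 0, 0))), 1)
  set.seed(3)
  a <- matrix(runif(150, 0, 10), 50, 3)
  b <- matrix(runif(150, 0, 10), 50, 3)
  expect_equal(amed(a, b), oracle_amed(a, b), tolerance = 1e-12)
  expect_equal(hausdorff(a, b), oracle_hausdorff(a, b), tolerance = 1e-12)
  expect_equal(amed(a, a), 0)
  expect_equal(hausdorff(a, a), 0)
  expect_gte(hausdorff(a, b), amed(a, b))
  expect_error(amed(a, matrix(numeric(0), 0, 3)), "nonempty")
})

test_that("Dice is symmetric in its arguments but FPR/FNR are not", {
  set.seed(4)
  p <- random_blob_mask()
  t_ <- random_blob_mask()
  expect_equal(dice(confusion_counts(p, t_)), dice(confusion_counts(t_, p)))
  expect_equal(mcc(confusion_counts(p, t_)), mcc(confusion_counts(t_, p)))
  # crafted pair: prediction = truth plus extra voxels
  tr <- array(FALSE, dim = c(8, 8, 8)); tr[3:5, 3:5, 3:5] <- TRUE
  pr <- tr; pr[6, 3:5, 3:5] <- TRUE
  f1 <- fpr_fnr(confusion_counts(binary_mask(pr), binary_mask(tr)))
  f2 <- fpr_fnr(confusion_counts(binary_mask(tr), binary_mask(pr)))
  expect_equal(f1$fpr, 9 / 27)
  expect_equal(f1$fnr, 0)
  expect_false(isTRUE(all.equal(f1, f2)))
})

test_that("the evaluation report bundles all eight metrics consistently", {
  set.seed(5)
  p <- random_blob_mask()
  t_ <- random_blob_mask()
  r <- evaluate_segmentation(p, t_)
  cc <- confusion_counts(p, t_)
  expect_equal(r$mcc, as.numeric(mcc(cc)))
  expect_equal(r$dsc, dice(cc))
  expect_equal(r$fpr, fpr_fnr(cc)$fpr)
  expect_equal(r$tp_pct, tp_fp_percent(cc)$tp_pct)
  sa <- extract_surface(p); sb <- extract_surface(t_)
  expect_equal(r$amed_mm, amed(sa, sb))
  expect_equal(r$hd_mm, hausdorff(sa, sb))

  perfect <- evaluate_segmentation(p, p)
  expect_equal(perfect$dsc, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$amed_mm, 0)
  expect_equal(perfect$hd_mm, 0)

  # JSON round-trip of the report
  f <- tempfile(fileext = ".json")
  write_report(r, f)
  back <- read_report(f)
  for (k in c("mcc", "dsc", "fpr", "fnr", "tp_pct", "fp_pct",
              "amed_mm", "hd_mm"))
    expect_equal(back[[k]], r[[k]], tolerance = 1e-12)
})
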