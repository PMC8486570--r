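mk <- function(vals, ...) {
  vals <- as.matrix(vals)
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("s%d", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- too_panel()[seq_len(ncol(vals))]
  mir_matrix(vals, ...)
}

test_that("same-patient replicates average to the arithmetic mean before normalization", {
  m <- mk(rbind(c(2, 4), c(4, 8), c(1, 1)))
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    patient_id = c("P1", "P1", "P2"),
    role = "reference_primary",
    class_label = c("LUAD", "LUAD", "CHOL"),
    sex = "male", stringsAsFactors = FALSE
  )
  out <- average_replicates(m, meta)
  expect_equal(nrow(out$matrix$values), 2)
  expect_equal(unname(out$matrix$values[1, ]), c(3, 6))
  expect_equal(out$meta$patient_id, c("P1", "P2"))

  # no replicates: identity
  meta2 <- meta; meta2$patient_id <- c("P1", "P2", "P3")
  out2 <- average_replicates(m, meta2)
  expect_equal(out2$matrix$values, m$values)

  # ordering contract: averaging after normalization is an error
  expect_error(average_replicates(normalize_median(m), meta), "before normalization")
  # class conflict
  meta3 <- meta; meta3$class_label <- c("LUAD", "CHOL", "CHOL")
  expect_error(average_replicates(m, meta3), "different class labels")
})

test_that("50th-percentile normalization sets every sample median to 1", {
  m <- mk(rbind(c(2, 4, 6), c(5, 5, 5)))
  nm <- normalize_median(m)
  expect_equal(unname(nm$values[1, ]), c(0.5, 1, 1.5))
  expect_equal(unname(nm$values[2, ]), c(1, 1, 1))
  expect_true(nm$normalized)

  big <- mk(matrix(rexp(40 * 89, rate = 0.01) + 0.5, 40, 89,
                   dimnames = list(sprintf("s%d", 1:40), too_panel())))
  nb <- normalize_median(big)
  expect_lt(max(abs(apply(nb$values, 1, median) - 1)), 1e-9)
  # idempotent up to the flag
  nb2 <- normalize_median(nb)
  expect_equal(nb2$values, nb$values)

  zero <- mk(rbind(c(0, 0, 0), c(1, 2, 3)))
  expect_error(normalize_median(zero), "s1")
})

test_that("control assays are excluded from the normalization median", {
  vals <- cbind(matrix(2, 1, 3), 1000)  # control column would distort the median
  colnames(vals) <- c(too_panel()[1:3], "UniSp6")
  rownames(vals) <- "s1"
  nm <- normalize_median(mir_matrix(vals))
  expect_equal(unname(nm$values[1, 1:3]), c(1, 1, 1))  # median over panel = 2
})

test_that("log transform uses log2(x + 0.01) and enforces its contracts", {
  m <- normalize_median(mk(rbind(c(1, 1, 1), c(2, 2, 2))))
  lt <- log_transform(m)
  expect_equal(lt$values[1, 1], log2(1.01), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(log_transform(lt), "already")
  raw <- mk(rbind(c(1, 2, 3)))
  expect_error(log_transform(raw), "normalized")
  # closed form at zero, monotonicity
  z <- mir_matrix(matrix(c(0, 0.5, 1, 7), 1, 4,
                         dimnames = list("s1", too_panel()[1:4])),
                  normalized = TRUE)
  lz <- log_transform(z)
  expect_equal(lz$values[1, 1], log2(0.01), ignore_attr = TRUE)
  expect_true(all(diff(lz$values[1, ]) > 0))
})

test_that("panel exclusions drop exactly the named assays", {
  full <- mk(matrix(1 + runif(2 * 89), 2, 89,
                    dimnames = list(c("a", "b"), too_panel())))
  ex <- exclude_mirnas(full)
  expect_equal(ncol(ex$values), 87)
  expect_false(any(default_exclusions() %in% mirna_ids(ex)))
  expect_identical(exclude_mirnas(full, character(0))$values, full$values)
  expect_error(exclude_mirnas(ex), "not in the matrix")  # double exclusion
  expect_error(exclude_mirnas(full, "miR-typo"), "not in the matrix")
})

test_that("class merging collapses 19 histological labels to 17 classes", {
  expect_equal(merge_classes(c("STAD", "CRC")), c("STAD-CRC", "STAD-CRC"))
  expect_equal(merge_classes(c("KIRC", "KIRP")), c("KICA", "KICA"))
  expect_equal(merge_classes("LUAD"), "LUAD")
  merged <- merge_classes(histology_classes())
  expect_equal(length(unique(merged)), 17)
  expect_setequal(unique(merged), prediction_classes())
  # idempotent
  expect_equal(merge_classes(merged), merged)
  expect_error(merge_classes("NOTACLASS"), "unknown class label")
})

test_that("detectability filter keeps samples first, then fully observed miRNAs", {
  set.seed(42)
  vals <- matrix(runif(100), 10, 10,
                 dimnames = list(sprintf("s%d", 1:10), too_panel()[1:10]))
  vals[1, 1:6] <- NA            # 60% missing -> dropped in step 1
  vals[2, 1] <- NA              # 10% missing -> survives step 1
  vals[5, 3] <- NA
  m <- detectability_filter(mir_matrix(vals), sample_frac = 0.8)

  # brute-force re-application of the two rules
  keep_s <- rowMeans(!is.na(vals)) >= 0.8
  keep_m <- colSums(is.na(vals[keep_s, ])) == 0
  expect_equal(rownames(m$values), names(which(keep_s)))
  expect_equal(colnames(m$values), names(which(keep_m)))
  expect_false(anyNA(m$values))

  full <- mir_matrix(matrix(1, 2, 2, dimnames = list(c("a", "b"), too_panel()[1:2])))
  expect_identical(detectability_filter(full)$values, full$values)
  allna <- mir_matrix(matrix(NA_real_, 2, 5,
                             dimnames = list(c("a", "b"), too_panel()[1:5])))
  expect_error(detectability_filter(allna), "every sample")
})

test_that("class mean/SD profiles match direct arithmetic", {
  vals <- rbind(c(1, 3), c(3, 5), c(10, 10))
  rownames(vals) <- c("a", "b", "c"); colnames(vals) <- too_panel()[1:2]
  prof <- class_mean_profiles(mir_matrix(vals), c("X", "X", "Y"))
  expect_equal(unname(prof$mean["X", ]), c(2, 4))
  expect_equal(unname(prof$sd["X", ]), c(sqrt(2), sqrt(2)))
  expect_true(all(is.na(prof$sd["Y", ])))   # singleton class: SD absent
  expect_equal(unname(prof$mean["Y", ]), c(10, 10))

  set.seed(1)
  big <- matrix(rnorm(300), 30, 10,
                dimnames = list(sprintf("s%d", 1:30), too_panel()[1:10]))
  lab <- rep(c("A", "B", "C"), each = 10)
  p2 <- class_mean_profiles(mir_matrix(abs(big)), lab)
  for (k in unique(lab)) {
    manual <- colSums(abs(big)[lab == k, ]) / 10
    expect_equal(unname(p2$mean[k, ]), unname(manual), tolerance = 1e-12)
  }
})

test_that("complete-linkage Manhattan clustering matches brute-force agglomeration", {
  expect_equal(sum(abs(c(0, 0) - c(1, 3))), 4)  # L1 arithmetic sanity
  set.seed(8)
  for (rep in 1:5) {
    x <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(letters[1:4], NULL))
    hc <- hierarchical_cluster(x)
    oracle <- oracle_complete_linkage(x)
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-12)
    for (step in seq_along(oracle$partitions)) {
      k <- 4 - step
      if (k >= 1) {
        expect_equal(hclust_partition(hc, k),
                     canon_partition(oracle$partitions[[step]]))
      }
    }
  }
  # identical profiles merge first at height 0
  x0 <- rbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  hc0 <- hierarchical_cluster(x0)
  expect_equal(hc0$height[1], 0)
  expect_equal(hclust_partition(hc0, 2), list(1:2, 3L))
  expect_error(hierarchical_cluster(x0[1, , drop = FALSE]), "at least two")
})
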