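test_that("fractional STD reproduces (I0 - Isat)/I0 with its limiting cases", {
  expect_identical(fractional_std(100, 100), 0)
  expect_equal(fractional_std(200, 198), 0.01)
  expect_identical(fractional_std(100, 0), 1)

  set.seed(11)
  I0 <- runif(1e4, 1e-3, 1e4)
  Isat <- I0 * runif(1e4, 0, 1)
  expect_identical(fractional_std(I0, Isat), (I0 - Isat) / I0)

  expect_error(fractional_std(0, 1), class = "stdepitope_invalid_input")
  expect_error(fractional_std(-5, 1), class = "stdepitope_invalid_input")
  # negative STD is an artefact: retained and warned, not clipped
  expect_warning(f <- fractional_std(100, 110), class = "stdepitope_artefact")
  expect_equal(f, -0.1)
})

test_that("relative STD anchors the most intense signal at exactly 100", {
  expect_equal(relative_std(c(Ha = 0.5, Hb = 1.0, Hc = 0.25)),
               c(Ha = 50, Hb = 100, Hc = 25))
  expect_equal(unname(relative_std(0.3)), 100)

  set.seed(21)
  for (i in 1:25) {
    abs_pct <- runif(sample(2:12, 1), 0.01, 2)
    rel <- relative_std(abs_pct)
    expect_identical(max(rel), 100)
    expect_true(all(rel >= 0 & rel <= 100))
    # scale invariance of the normalisation
    expect_equal(relative_std(abs_pct * 7.3), rel)
  }
  expect_error(relative_std(c(0, -1)), class = "stdepitope_no_signal")
})

test_that("epitope colour classes follow the strict over-thresholds", {
  expect_equal(as.character(classify_epitope(c(85, 50, 30))),
               c("DARK_RED", "ORANGE", "LIME"))
  expect_equal(as.character(classify_epitope(100, is_max = TRUE)), "MAX")
  # boundary convention: exactly 80 -> ORANGE, exactly 40 -> LIME
  expect_equal(as.character(classify_epitope(c(80, 40))), c("ORANGE", "LIME"))

  grid <- seq(0, 100, by = 0.01)
  expect_equal(as.character(classify_epitope(grid)),
               vapply(grid, oracle_epitope_class, character(1),
                      is_max = FALSE))
  expect_error(classify_epitope(101), class = "stdepitope_invalid_input")
  expect_error(classify_epitope(-0.5), class = "stdepitope_invalid_input")
})

test_that("absolute STD bins round to one decimal, closing the printed gaps", {
  expect_equal(as.character(bin_absolute(c(1.2, 0.95, 0.15))),
               c("GT_1", "R10_09", "LT_02"))
  grid <- seq(0, 1.5, by = 0.01)
  expect_equal(as.character(bin_absolute(grid)),
               vapply(grid, oracle_abs_bin, character(1)))
  expect_warning(b <- bin_absolute(-0.3), class = "stdepitope_artefact")
  expect_equal(as.character(b), "LT_02")
})

test_that("binder detection uses a strict noise floor", {
  mk <- function(abs_pct) {
    tibble::tibble(compound_id = "c", proton_label = paste0("H", seq_along(abs_pct)),
                   I0 = 100, Isat = 100 * (1 - abs_pct / 100))
  }
  expect_false(detect_binding(mk(c(0, 0, 0)), 0.05)$binder)
  expect_true(detect_binding(mk(c(1.0, 0)), 0.05)$binder)
  # all protons exactly at the floor: strict inequality, no binder
  expect_false(detect_binding(mk(c(0.05, 0.05)), 0.05)$binder)
})

test_that("quantification labels protons and compounds consistently", {
  peaks <- tibble::tibble(
    compound_id = rep(c("b", "nb"), each = 3),
    proton_label = rep(c("H1", "H2", "H3"), 2),
    I0 = 100,
    Isat = c(99, 99.5, 99.9, 100, 100, 100)
  )
  prof <- std_quantify(peaks, noise_floor_pct = 0.05)
  b <- prof[prof$compound_id == "b", ]
  nb <- prof[prof$compound_id == "nb", ]
  expect_true(all(b$binder))
  expect_equal(sum(b$epitope_class == "MAX"), 1L)
  expect_equal(b$relative_std_pct[b$is_max], 100)
  # non-binders have relative values and classes left unset
  expect_false(any(nb$binder))
  expect_true(all(is.na(nb$relative_std_pct)))
  expect_true(all(is.na(nb$epitope_class)))

  dup <- peaks
  dup$proton_label <- "H1"
  expect_error(std_quantify(dup), class = "stdepitope_invalid_input")
})

test_that("relative values and classes are invariant under common rescaling", {
  set.seed(31)
  peaks <- tibble::tibble(
    compound_id = "c1", proton_label = sprintf("H%d", 1:8),
    I0 = runif(8, 50, 200))
  peaks$Isat <- peaks$I0 * (1 - runif(8, 0.0005, 0.015))
  for (c_scale in c(0.01, 1, 7.3, 1e4)) {
    scaled <- dplyr::mutate(peaks, I0 = I0 * c_scale, Isat = Isat * c_scale)
    p1 <- std_quantify(peaks)
    p2 <- std_quantify(scaled)
    expect_equal(p2$relative_std_pct, p1$relative_std_pct)
    expect_equal(p2$epitope_class, p1$epitope_class)
    expect_equal(p2$binder, p1$binder)
  }
})

test_that("bin counts conserve the number of above-floor protons", {
  peaks <- tibble::tibble(
    compound_id = "c1", proton_label = c("Ha", "Hb", "Hc", "Hd"),
    I0 = 100, Isat = 100 * (1 - c(1.2, 0.3, 0.3, 0.1) / 100))
  counts <- count_by_bin(std_quantify(peaks, noise_floor_pct = 0.05))
  expect_equal(counts$GT_1, 1L)
  expect_equal(counts$R04_02, 2L)
  expect_equal(counts$LT_02, 1L)
  expect_equal(sum(counts[, -1]), 4L)

  empty <- std_quantify(peaks[0, ])
  expect_equal(nrow(count_by_bin(empty)), 0L)

  # row sums match above-floor counts on a random panel
  set.seed(41)
  pk <- tibble::tibble(
    compound_id = rep(sprintf("c%d", 1:5), each = 9),
    proton_label = rep(sprintf("H%d", 1:9), 5),
    I0 = 100, Isat = 100 * (1 - runif(45, 0, 0.02)))
  prof <- std_quantify(pk)
  ct <- count_by_bin(prof)
  by_cpd <- tapply(prof$above_floor, prof$compound_id, sum)
  expect_equal(rowSums(ct[, -1]), as.numeric(by_cpd[ct$compound_id]),
               ignore_attr = TRUE)
})
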