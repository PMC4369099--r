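test_that("an empty field yields background-only stacks and no truth", {
  cfg <- synth_config(n_cells = 0, field_shape_zyx = c(8, 64, 64), seed = 1)
  exp <- generate_experiment(cfg)
  expect_equal(nrow(exp$truth), 0)
  expect_true(all(exp$cell_labels == 0))
  expect_equal(dim(exp$stacks$rna), c(8, 64, 64))
  # background + noise only: nothing anywhere near spot amplitude
  expect_lt(max(exp$stacks$rna),
            cfg$background_offset + cfg$background_gradient +
              6 * cfg$noise_sd)
})

test_that("nuclear_fraction = 1 confines every molecule to the nucleus mask", {
  exp <- generate_experiment(synth_config(
    n_cells = 1, field_shape_zyx = c(12, 64, 64),
    count_model = count_model("poisson", mean = 50),
    nuclear_fraction = 1, seed = 2))
  tr <- exp$truth[exp$truth$channel == "rna", ]
  lab <- exp$nucleus_labels[cbind(round(tr$y) + 1, round(tr$x) + 1)]
  expect_true(all(lab == tr$cell_id))
  expect_true(all(tr$in_nucleus))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synth_config(n_cells = 2, field_shape_zyx = c(10, 80, 80),
                      count_model = count_model("poisson", mean = 20),
                      dual_label = TRUE, autofluor_density = 2, seed = 9)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$stacks, b$stacks)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cell_labels, b$cell_labels)
})

test_that("ground truth is internally consistent", {
  exp <- generate_experiment(synth_config(
    n_cells = 3, field_shape_zyx = c(12, 160, 160),
    count_model = count_model("poisson", mean = 30),
    foci_spec = list(n_foci = 2, molecules = 6),
    autofluor_density = 3, seed = 4))
  tr <- exp$truth
  # every molecule lies inside its own cell mask
  lab <- exp$cell_labels[cbind(round(tr$y) + 1, round(tr$x) + 1)]
  expect_true(all(lab == tr$cell_id))
  # nuclear flags agree with the nucleus mask
  nlab <- exp$nucleus_labels[cbind(round(tr$y) + 1, round(tr$x) + 1)]
  expect_identical(tr$in_nucleus, nlab == tr$cell_id)
  # focus members are nuclear and tightly packed
  foci <- tr[!is.na(tr$focus_id), ]
  expect_true(all(foci$in_nucleus))
  spread <- foci %>%
    dplyr::group_by(cell_id, focus_id) %>%
    dplyr::summarise(diameter = max(dist(cbind(y, x))),
                     n = dplyr::n(), .groups = "drop")
  expect_true(all(spread$diameter <= 4 + 1e-9))  # 2 px radius disc
  expect_true(all(spread$n == 6))
  # autofluorescent particles appear in gfp and are duplicated in rna
  af_gfp <- tr[tr$channel == "gfp", ]
  af_rna <- tr[tr$channel == "rna" & tr$kind == "autofluor", ]
  expect_true(all(af_gfp$kind == "autofluor"))
  expect_equal(nrow(af_gfp), nrow(af_rna))
  expect_equal(af_gfp[, c("y", "x")], af_rna[, c("y", "x")])
})

test_that("dual-label channels share molecules with bounded jitter plus shift", {
  shift <- c(2, 1)
  exp <- generate_experiment(synth_config(
    n_cells = 1, field_shape_zyx = c(12, 96, 96),
    count_model = count_model("poisson", mean = 30),
    dual_label = TRUE, channel_shift_px = shift, seed = 5))
  ev <- exp$truth[exp$truth$channel == "even", ]
  od <- exp$truth[exp$truth$channel == "odd", ]
  expect_setequal(ev$mol_id, od$mol_id)
  od <- od[match(ev$mol_id, od$mol_id), ]
  # displacement = shift + (jitter_odd - jitter_even), each jitter <= 0.5 px
  expect_true(all(abs(od$y - ev$y - shift[1]) <= 1))
  expect_true(all(abs(od$x - ev$x - shift[2]) <= 1))
})

test_that("rogue signal lands in exactly one dual-label channel", {
  exp <- generate_experiment(synth_config(
    n_cells = 1, field_shape_zyx = c(12, 96, 96),
    count_model = count_model("poisson", mean = 10),
    dual_label = TRUE,
    rogue_signal = list(n_foci = 1, molecules = 12, amp_factor = 2),
    seed = 6))
  rogue <- exp$truth[exp$truth$kind == "rogue", ]
  expect_equal(unique(rogue$channel), "even")
  expect_equal(nrow(rogue), 12)
})

test_that("mitotic cells carry no nuclear foci", {
  exp <- generate_experiment(synth_config(
    n_cells = 4, field_shape_zyx = c(10, 160, 160),
    count_model = count_model("poisson", mean = 10),
    foci_spec = list(n_foci = 2, molecules = 6),
    mitotic_fraction = 0.5, seed = 8))
  mit <- exp$cells$cell_id[exp$cells$mitotic]
  expect_true(length(mit) > 0)  # seed chosen blind; guards fixture validity
  foci_cells <- unique(exp$truth$cell_id[!is.na(exp$truth$focus_id)])
  expect_length(intersect(foci_cells, mit), 0)
})

test_that("a field too small for its cells is rejected", {
  expect_error(synth_config(n_cells = 50, field_shape_zyx = c(8, 64, 64)),
               class = "lincfish_config_error")
})
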