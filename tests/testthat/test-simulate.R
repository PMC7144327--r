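smallCfg <- function(seed = 1, ...) {
  simulationConfig(seed = seed, n_synapses = 3,
                   field_size_nm = c(4000, 4000, 2000), ...)
}

test_that("a scene without synapses holds only background GLT-1", {
  sc <- makeScene(simulationConfig(seed = 1, n_synapses = 0))
  expect_equal(nrow(sc@synapses), 0L)
  expect_true(all(sc@molecules$component == "background"))
  expect_true(all(sc@molecules$channel == "GLT1"))
})

test_that("pre/post layer centres are separated exactly as configured", {
  for (seed in c(1, 7, 99)) {
    sc <- makeScene(smallCfg(seed))
    sep <- sqrt((sc@synapses$pre_x - sc@synapses$post_x)^2 +
                (sc@synapses$pre_y - sc@synapses$post_y)^2 +
                (sc@synapses$pre_z - sc@synapses$post_z)^2)
    expect_equal(sep, rep(120, nrow(sc@synapses)))
  }
})

test_that("shell molecule count and field containment hold by construction", {
  cfg <- simulationConfig(seed = 3, n_synapses = 10,
                          glt1_molecules_per_synapse = 80)
  sc <- makeScene(cfg)
  expect_equal(sum(sc@molecules$component == "shell"), 800L)
  L <- cfg@field_size_nm
  expect_true(all(sc@molecules$x_nm >= 0 & sc@molecules$x_nm <= L[1]))
  expect_true(all(sc@molecules$y_nm >= 0 & sc@molecules$y_nm <= L[2]))
  expect_true(all(abs(sc@molecules$z_nm) <= L[3] / 2))
  # shell radii live inside the configured shell (around shifted centre)
  sh <- sc@molecules[sc@molecules$component == "shell", ]
  ctr <- sc@synapses[match(sh$synapse_id, sc@synapses$synapse_id), ]
  scx <- ctr$cx_nm + ctr$ax * cfg@glt1_post_shift_nm
  scy <- ctr$cy_nm + ctr$ay * cfg@glt1_post_shift_nm
  scz <- ctr$cz_nm + ctr$az * cfg@glt1_post_shift_nm
  r <- sqrt((sh$x_nm - scx)^2 + (sh$y_nm - scy)^2 + (sh$z_nm - scz)^2)
  expect_true(all(r >= cfg@glt1_inner_nm - 1e-9 &
                  r <= cfg@glt1_outer_nm + 1e-9))
})

test_that("an overcrowded field raises a placement error", {
  expect_error(makeScene(simulationConfig(
    seed = 1, n_synapses = 40, field_size_nm = c(2500, 2500, 2000))),
    "field too small")
})

test_that("identical seeds give bit-identical scenes and tables", {
  cfg <- smallCfg(11)
  t1 <- imageScene(makeScene(cfg))
  t2 <- imageScene(makeScene(cfg))
  expect_identical(locData(t1), locData(t2))
  expect_identical(truthTable(t1), truthTable(t2))
  t3 <- imageScene(makeScene(smallCfg(12)))
  expect_false(identical(locData(t1), locData(t3)))
})

test_that("the noiseless generator reproduces molecule positions exactly", {
  cfg <- smallCfg(5, labelling_efficiency = 1, blinks_per_fluorophore = 1,
                  sigma_xy_nm = 1e-9, sigma_z_nm = 1e-9,
                  label_displacement_sigma_nm = 1e-12,
                  chromatic_offset_nm = rbind(GLT1 = c(0, 0, 0),
                                              bassoon = c(0, 0, 0),
                                              Homer1 = c(0, 0, 0)),
                  false_loc_density_per_um3_per_channel = 1e-12)
  sc <- makeScene(cfg)
  tab <- imageScene(sc)
  tr <- truthTable(tab)
  expect_equal(nLocs(tab), nrow(sc@molecules))
  m <- sc@molecules[match(tr$molecule_id, sc@molecules$molecule_id), ]
  err <- sqrt((locData(tab)$x_nm - m$x_nm)^2 +
              (locData(tab)$y_nm - m$y_nm)^2 +
              (locData(tab)$z_nm - m$z_nm)^2)
  expect_lt(max(err), 1e-5)
})

test_that("zero labelling efficiency leaves only spurious localisations", {
  cfg <- smallCfg(6, labelling_efficiency = 1e-12)
  tab <- imageScene(makeScene(cfg))
  expect_true(all(is.na(truthTable(tab)$molecule_id)))
})

test_that("every non-spurious localisation traces to exactly one molecule", {
  cfg <- smallCfg(8)
  sc <- makeScene(cfg)
  tab <- imageScene(sc)
  tr <- truthTable(tab)
  expect_equal(nrow(tr), nLocs(tab))
  real <- tr[!is.na(tr$molecule_id), ]
  expect_true(all(real$molecule_id %in% sc@molecules$molecule_id))
})

test_that("localisation counts match the analytic expectation over seeds", {
  counts <- vapply(1:50, function(s) {
    sc <- makeScene(smallCfg(s))
    sum(locData(imageScene(sc))$channel == "bassoon")
  }, numeric(1))
  sc1 <- makeScene(smallCfg(1))
  expected <- expectedLocCount(sc1, "bassoon")
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
})

test_that("localisation-to-molecule displacement has the predicted RMS", {
  cfg <- simulationConfig(seed = 21, n_synapses = 8,
                          field_size_nm = c(6000, 6000, 2000))
  tab <- imageScene(makeScene(cfg))
  tr <- truthTable(tab)
  real <- !is.na(tr$molecule_id)
  d2 <- (locData(tab)$x_nm[real] - tr$mol_x_nm[real])^2 +
        (locData(tab)$y_nm[real] - tr$mol_y_nm[real])^2 +
        (locData(tab)$z_nm[real] - tr$mol_z_nm[real])^2
  # chromatic offsets are deterministic shifts; remove them per channel
  offs <- cfg@chromatic_offset_nm[locData(tab)$channel[real], , drop = FALSE]
  d2 <- (locData(tab)$x_nm[real] - offs[, 1] - tr$mol_x_nm[real])^2 +
        (locData(tab)$y_nm[real] - offs[, 2] - tr$mol_y_nm[real])^2 +
        (locData(tab)$z_nm[real] - offs[, 3] - tr$mol_z_nm[real])^2
  rms <- sqrt(mean(d2))
  pred <- sqrt(2 * cfg@sigma_xy_nm^2 + cfg@sigma_z_nm^2 +
               3 * cfg@label_displacement_sigma_nm^2)
  expect_lt(abs(rms - pred) / pred, 0.1)
})
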