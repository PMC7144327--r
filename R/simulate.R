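#' Construct a SimulationConfig
#'
#' Defaults describe the study conditions the generator emulates: a 10 x 10
#' x 2 um field holding disc-shaped pre/postsynaptic label layers in
#' trans-synaptic apposition 120 nm apart, perisynaptic GLT-1 shells
#' enriched toward the postsynaptic side, realistic antibody-linkage
#' displacement, stochastic blinking, anisotropic localisation noise,
#' sub-30-nm chromatic offsets and sparse spurious localisations.
#'
#' @param seed RNG seed; the whole scene and localisation table are a pure
#'   function of it
#' @param field_size_nm field extents (Lx, Ly, Lz) in nm; z spans
#'   `[-Lz/2, Lz/2]`
#' @param n_synapses number of synapses to place
#' @param synapse_separation_nm trans-synaptic distance between the pre- and
#'   postsynaptic label-layer centres
#' @param min_synapse_spacing_nm minimum centre-to-centre spacing between
#'   synapses (rejection-sampled)
#' @param disc_radius_nm radius of the label discs
#' @param disc_thickness_sigma_nm Gaussian axial thickness of the discs
#' @param molecules_per_disc scaffold molecules per label disc
#' @param glt1_inner_nm,glt1_outer_nm GLT-1 shell radii around the synapse
#' @param glt1_molecules_per_synapse GLT-1 molecules per shell
#' @param glt1_post_shift_nm shell-centre shift toward the postsynaptic disc
#' @param glt1_background_density_per_um3 diffuse GLT-1 background density
#' @param label_displacement_sigma_nm antibody-linkage displacement (per
#'   axis, isotropic)
#' @param labelling_efficiency fraction of molecules carrying a detectable
#'   fluorophore
#' @param blinks_per_fluorophore mean localisations per fluorophore
#'   (1 + geometric law)
#' @param sigma_xy_nm,sigma_z_nm lateral (per axis) and axial localisation
#'   noise
#' @param chromatic_offset_nm matrix (channels x 3) of per-channel constant
#'   offsets in nm
#' @param false_loc_density_per_um3_per_channel spurious localisation
#'   density
#' @param n_frames number of acquisition frames localisations are spread
#'   over
#' @param photons_mean mean photon count per localisation
#' @param bg_photons camera background, photons per pixel
#' @param pixel_size_nm camera pixel size for rendered frames
#' @param fov_px rendered frame side length in pixels
#' @param psf_w0_nm in-focus PSF Gaussian width
#' @param psf_zr_nm PSF axial range parameter (width doubles at
#'   `sqrt(3)*psf_zr_nm` defocus)
#' @param biplane_offset_nm axial distance between the two detection planes
#' @param channels a [ChannelSet-class]
#' @return a validated [SimulationConfig-class]
#' @examples
#' cfg <- simulationConfig(seed = 1, n_synapses = 5)
#' @export
simulationConfig <- function(
    seed = 1,
    field_size_nm = c(10000, 10000, 2000),
    n_synapses = 50,
    synapse_separation_nm = 120,
    min_synapse_spacing_nm = 1200,
    disc_radius_nm = 150,
    disc_thickness_sigma_nm = 15,
    molecules_per_disc = 60,
    glt1_inner_nm = 40,
    glt1_outer_nm = 250,
    glt1_molecules_per_synapse = 80,
    glt1_post_shift_nm = 20,
    glt1_background_density_per_um3 = 5,
    label_displacement_sigma_nm = 12,
    labelling_efficiency = 0.7,
    blinks_per_fluorophore = 4,
    sigma_xy_nm = 10,
    sigma_z_nm = 25,
    chromatic_offset_nm = rbind(GLT1 = c(0, 0, 0),
                                bassoon = c(15, -10, 20),
                                Homer1 = c(-12, 8, -25)),
    false_loc_density_per_um3_per_channel = 1,
    n_frames = 10000,
    photons_mean = 1000,
    bg_photons = 5,
    pixel_size_nm = 100,
    fov_px = 64,
    psf_w0_nm = 150,
    psf_zr_nm = 500,
    biplane_offset_nm = 500,
    channels = channelSet()) {
  new("SimulationConfig", seed = seed, field_size_nm = field_size_nm,
      n_synapses = n_synapses,
      synapse_separation_nm = synapse_separation_nm,
      min_synapse_spacing_nm = min_synapse_spacing_nm,
      disc_radius_nm = disc_radius_nm,
      disc_thickness_sigma_nm = disc_thickness_sigma_nm,
      molecules_per_disc = molecules_per_disc,
      glt1_inner_nm = glt1_inner_nm, glt1_outer_nm = glt1_outer_nm,
      glt1_molecules_per_synapse = glt1_molecules_per_synapse,
      glt1_post_shift_nm = glt1_post_shift_nm,
      glt1_background_density_per_um3 = glt1_background_density_per_um3,
      label_displacement_sigma_nm = label_displacement_sigma_nm,
      labelling_efficiency = labelling_efficiency,
      blinks_per_fluorophore = blinks_per_fluorophore,
      sigma_xy_nm = sigma_xy_nm, sigma_z_nm = sigma_z_nm,
      chromatic_offset_nm = chromatic_offset_nm,
      false_loc_density_per_um3_per_channel =
        false_loc_density_per_um3_per_channel,
      n_frames = n_frames, photons_mean = photons_mean,
      bg_photons = bg_photons, pixel_size_nm = pixel_size_nm,
      fov_px = fov_px, psf_w0_nm = psf_w0_nm, psf_zr_nm = psf_zr_nm,
      biplane_offset_nm = biplane_offset_nm, channels = channels)
}

# role -> channel lookup
roleChannel <- function(cfg, role) {
  names(cfg@channels@roles)[cfg@channels@roles == role][1]
}

# Margin keeping every synapse-attached molecule inside the field.
sceneMargin <- function(cfg) {
  max(cfg@synapse_separation_nm / 2 + cfg@disc_radius_nm +
        4 * cfg@disc_thickness_sigma_nm +
        4 * cfg@label_displacement_sigma_nm,
      cfg@glt1_outer_nm + cfg@glt1_post_shift_nm +
        cfg@synapse_separation_nm / 2) + 10
}

#' Generate a ground-truth tripartite-synapse scene
#'
#' Synapse centres are uniform in the field (kept a margin away from the
#' borders so all attached molecules stay inside) with a minimum spacing,
#' rejection-sampled; axes are isotropically random. Pre- and postsynaptic
#' label layers are discs perpendicular to the axis whose centres are
#' exactly `synapse_separation_nm` apart; GLT-1 molecules occupy a
#' spherical shell around each synapse centre (shifted toward the
#' postsynaptic disc) plus a uniform background. Fully reproducible from
#' `cfg@seed`.
#'
#' @param cfg a [SimulationConfig-class]
#' @return a [GroundTruthScene-class]
#' @export
makeScene <- function(cfg) {
  validObject(cfg)
  withSeed(deriveSeed(cfg@seed, 1), {
    L <- cfg@field_size_nm
    margin <- sceneMargin(cfg)
    if (cfg@n_synapses > 0 &&
        (L[1] <= 2 * margin || L[2] <= 2 * margin || L[3] <= 2 * margin))
      stop("field too small for the synapse margin")
    centres <- matrix(numeric(0), 0, 3)
    tries <- 0L
    max_tries <- 1000L * max(cfg@n_synapses, 1L)
    while (nrow(centres) < cfg@n_synapses) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("field too small to place ", cfg@n_synapses,
             " synapses with spacing ", cfg@min_synapse_spacing_nm, " nm")
      cand <- c(stats::runif(1, margin, L[1] - margin),
                stats::runif(1, margin, L[2] - margin),
                stats::runif(1, -L[3] / 2 + margin, L[3] / 2 - margin))
      if (nrow(centres) == 0L ||
          min(crossDist2(matrix(cand, 1), centres)) >=
            cfg@min_synapse_spacing_nm^2)
        centres <- rbind(centres, cand)
    }
    n_syn <- cfg@n_synapses
    syn <- NULL
    mols <- list()
    sampleDisc <- function(centre, axis, n) {
      B <- perpBasis(axis)
      r <- cfg@disc_radius_nm * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      ax_off <- stats::rnorm(n, 0, cfg@disc_thickness_sigma_nm)
      sweep((r * cos(th)) %o% B[1, ] + (r * sin(th)) %o% B[2, ] +
              ax_off %o% axis, 2, centre, "+")
    }
    if (n_syn > 0) {
      axes <- matrix(stats::rnorm(3 * n_syn), n_syn, 3)
      axes <- axes / sqrt(rowSums(axes^2))
      pre_c <- centres - axes * cfg@synapse_separation_nm / 2
      post_c <- centres + axes * cfg@synapse_separation_nm / 2
      syn <- data.frame(synapse_id = seq_len(n_syn) - 1L,
                        cx_nm = centres[, 1], cy_nm = centres[, 2],
                        cz_nm = centres[, 3],
                        ax = axes[, 1], ay = axes[, 2], az = axes[, 3],
                        pre_x = pre_c[, 1], pre_y = pre_c[, 2],
                        pre_z = pre_c[, 3],
                        post_x = post_c[, 1], post_y = post_c[, 2],
                        post_z = post_c[, 3])
      pre_ch <- roleChannel(cfg, "presynaptic")
      post_ch <- roleChannel(cfg, "postsynaptic")
      for (s in seq_len(n_syn)) {
        M <- cfg@molecules_per_disc
        Pp <- sampleDisc(pre_c[s, ], axes[s, ], M)
        mols[[length(mols) + 1L]] <- data.frame(
          channel = pre_ch, x_nm = Pp[, 1], y_nm = Pp[, 2], z_nm = Pp[, 3],
          synapse_id = s - 1L, component = "disc")
        Pq <- sampleDisc(post_c[s, ], axes[s, ], M)
        mols[[length(mols) + 1L]] <- data.frame(
          channel = post_ch, x_nm = Pq[, 1], y_nm = Pq[, 2], z_nm = Pq[, 3],
          synapse_id = s - 1L, component = "disc")
        # GLT-1 shell, centred slightly toward the postsynaptic side
        ns <- cfg@glt1_molecules_per_synapse
        if (ns > 0) {
          u <- stats::runif(ns)
          rad <- (u * (cfg@glt1_outer_nm^3 - cfg@glt1_inner_nm^3) +
                    cfg@glt1_inner_nm^3)^(1 / 3)
          dirs <- matrix(stats::rnorm(3 * ns), ns, 3)
          dirs <- dirs / sqrt(rowSums(dirs^2))
          sc <- centres[s, ] + axes[s, ] * cfg@glt1_post_shift_nm
          P <- sweep(dirs * rad, 2, sc, "+")
          mols[[length(mols) + 1L]] <- data.frame(
            channel = roleChannel(cfg, "perisynaptic"),
            x_nm = P[, 1], y_nm = P[, 2], z_nm = P[, 3],
            synapse_id = s - 1L, component = "shell")
        }
      }
    } else {
      syn <- data.frame(synapse_id = integer(0), cx_nm = numeric(0),
                        cy_nm = numeric(0), cz_nm = numeric(0),
                        ax = numeric(0), ay = numeric(0), az = numeric(0),
                        pre_x = numeric(0), pre_y = numeric(0),
                        pre_z = numeric(0), post_x = numeric(0),
                        post_y = numeric(0), post_z = numeric(0))
    }
    # uniform GLT-1 background
    vol_um3 <- prod(L) / 1e9
    nbg <- stats::rpois(1, cfg@glt1_background_density_per_um3 * vol_um3)
    if (nbg > 0) {
      mols[[length(mols) + 1L]] <- data.frame(
        channel = roleChannel(cfg, "perisynaptic"),
        x_nm = stats::runif(nbg, 0, L[1]),
        y_nm = stats::runif(nbg, 0, L[2]),
        z_nm = stats::runif(nbg, -L[3] / 2, L[3] / 2),
        synapse_id = NA_integer_, component = "background")
    }
    molecules <- if (length(mols)) do.call(rbind, mols) else
      data.frame(channel = character(0), x_nm = numeric(0),
                 y_nm = numeric(0), z_nm = numeric(0),
                 synapse_id = integer(0), component = character(0))
    molecules <- cbind(molecule_id = seq_len(nrow(molecules)) - 1L, molecules)
    rownames(molecules) <- NULL
    new("GroundTruthScene", molecules = molecules, synapses = syn,
        config = cfg)
  })
}

#' Image a ground-truth scene through the generative dSTORM model
#'
#' Each molecule is labelled with probability `labelling_efficiency`;
#' labelled molecules carry one fluorophore displaced by an isotropic
#' Gaussian (antibody linkage); each fluorophore yields `1 + Geometric`
#' localisations (mean `blinks_per_fluorophore`); each localisation adds
#' anisotropic Gaussian noise and the channel's chromatic offset. Spurious
#' localisations are added uniformly per channel. Frames are assigned
#' uniformly at random. Ground-truth provenance is kept in the sidecar
#' (`truthTable()`): one generating molecule per non-spurious localisation.
#'
#' @param scene a [GroundTruthScene-class]
#' @param cfg the [SimulationConfig-class] (defaults to the scene's)
#' @return a [LocalizationTable-class]; sidecar in `locMeta(x)$truth`
#' @export
imageScene <- function(scene, cfg = scene@config) {
  withSeed(deriveSeed(cfg@seed, 2), {
    L <- cfg@field_size_nm
    out <- list(); truth <- list()
    for (ch in cfg@channels@names) {
      m <- scene@molecules[scene@molecules$channel == ch, , drop = FALSE]
      nm <- nrow(m)
      if (nm > 0) {
        lab <- stats::runif(nm) < cfg@labelling_efficiency
        m <- m[lab, , drop = FALSE]
        nf <- nrow(m)
      } else nf <- 0L
      if (nf > 0) {
        fl <- cbind(m$x_nm, m$y_nm, m$z_nm) +
          matrix(stats::rnorm(3 * nf, 0, cfg@label_displacement_sigma_nm),
                 nf, 3)
        K <- if (cfg@blinks_per_fluorophore > 1)
          1L + stats::rgeom(nf, 1 / cfg@blinks_per_fluorophore)
        else rep(1L, nf)
        idx <- rep(seq_len(nf), K)
        nl <- length(idx)
        P <- fl[idx, , drop = FALSE] +
          cbind(stats::rnorm(nl, 0, cfg@sigma_xy_nm),
                stats::rnorm(nl, 0, cfg@sigma_xy_nm),
                stats::rnorm(nl, 0, cfg@sigma_z_nm))
        P <- sweep(P, 2, cfg@chromatic_offset_nm[ch, ], "+")
      } else {
        P <- matrix(numeric(0), 0, 3); idx <- integer(0); nl <- 0L
      }
      nfalse <- stats::rpois(1, cfg@false_loc_density_per_um3_per_channel *
                                 prod(L) / 1e9)
      F <- cbind(stats::runif(nfalse, 0, L[1]),
                 stats::runif(nfalse, 0, L[2]),
                 stats::runif(nfalse, -L[3] / 2, L[3] / 2))
      allP <- rbind(P, F)
      ntot <- nrow(allP)
      out[[ch]] <- data.frame(
        channel = ch,
        frame = if (ntot) sample.int(cfg@n_frames, ntot, replace = TRUE) - 1L
                else integer(0),
        x_nm = allP[, 1], y_nm = allP[, 2], z_nm = allP[, 3],
        photons = stats::rlnorm(ntot, log(cfg@photons_mean) - 0.045, 0.3),
        bg = rep(cfg@bg_photons, ntot),
        sigma_xy_nm = rep(cfg@sigma_xy_nm, ntot),
        sigma_z_nm = rep(cfg@sigma_z_nm, ntot))
      truth[[ch]] <- data.frame(
        channel = ch,
        molecule_id = c(m$molecule_id[idx], rep(NA_integer_, nfalse)),
        synapse_id = c(m$synapse_id[idx], rep(NA_integer_, nfalse)),
        true_x_nm = c(if (nl) fl[idx, 1] else numeric(0), F[, 1]),
        true_y_nm = c(if (nl) fl[idx, 2] else numeric(0), F[, 2]),
        true_z_nm = c(if (nl) fl[idx, 3] else numeric(0), F[, 3]),
        mol_x_nm = c(m$x_nm[idx], rep(NA_real_, nfalse)),
        mol_y_nm = c(m$y_nm[idx], rep(NA_real_, nfalse)),
        mol_z_nm = c(m$z_nm[idx], rep(NA_real_, nfalse)))
    }
    d <- do.call(rbind, out)
    tr <- do.call(rbind, truth)
    tr <- cbind(loc_id = seq_len(nrow(tr)) - 1L, tr)
    rownames(tr) <- NULL
    localizationTable(d, list(
      pixel_size_nm = cfg@pixel_size_nm, axial_range_nm = L[3],
      channels = cfg@channels@names,
      source = sprintf("simulated(seed=%g)", cfg@seed),
      truth = tr))
  })
}

#' Ground-truth sidecar of a simulated localisation table
#'
#' @param table a table produced by [imageScene()]
#' @return data.frame mapping each localisation to its generating molecule
#'   (`molecule_id` NA for spurious localisations), fluorophore position
#'   (`true_*`) and epitope position (`mol_*`)
#' @export
truthTable <- function(table) {
  tr <- table@meta$truth
  if (is.null(tr)) stop("table carries no ground-truth sidecar")
  tr
}

#' Analytic expectation of the localisation count of a channel
#'
#' `n_molecules x efficiency x mean_blinks + false_density x volume`.
#'
#' @param scene a [GroundTruthScene-class]
#' @param channel channel label
#' @param cfg the [SimulationConfig-class]
#' @return expected number of localisations
#' @export
expectedLocCount <- function(scene, channel, cfg = scene@config) {
  nm <- sum(scene@molecules$channel == channel)
  nm * cfg@labelling_efficiency * cfg@blinks_per_fluorophore +
    cfg@false_loc_density_per_um3_per_channel * prod(cfg@field_size_nm) / 1e9
}

#' Simulate a multi-colour fiducial-bead localisation table
#'
#' Beads are bright multi-colour fiducials visible in every channel at
#' identical true positions; each channel sees them displaced by its
#' chromatic offset and localised `locs_per_bead` times with the
#' configured localisation noise. Used to estimate channel-registration
#' transforms.
#'
#' @param cfg a [SimulationConfig-class]
#' @param n_beads number of beads
#' @param locs_per_bead localisations per bead and channel
#' @return a [LocalizationTable-class] with a `bead_id` column
#' @export
makeBeadTable <- function(cfg, n_beads = 12, locs_per_bead = 500) {
  withSeed(deriveSeed(cfg@seed, 3), {
    L <- cfg@field_size_nm
    B <- cbind(stats::runif(n_beads, 500, L[1] - 500),
               stats::runif(n_beads, 500, L[2] - 500),
               stats::runif(n_beads, -L[3] / 2 + 200, L[3] / 2 - 200))
    out <- list()
    for (ch in cfg@channels@names) {
      idx <- rep(seq_len(n_beads), each = locs_per_bead)
      n <- length(idx)
      P <- B[idx, , drop = FALSE] +
        cbind(stats::rnorm(n, 0, cfg@sigma_xy_nm),
              stats::rnorm(n, 0, cfg@sigma_xy_nm),
              stats::rnorm(n, 0, cfg@sigma_z_nm))
      P <- sweep(P, 2, cfg@chromatic_offset_nm[ch, ], "+")
      out[[ch]] <- data.frame(
        channel = ch, frame = seq_len(n) - 1L,
        x_nm = P[, 1], y_nm = P[, 2], z_nm = P[, 3],
        photons = rep(5000, n), bg = rep(cfg@bg_photons, n),
        sigma_xy_nm = rep(cfg@sigma_xy_nm, n),
        sigma_z_nm = rep(cfg@sigma_z_nm, n),
        bead_id = idx - 1L)
    }
    localizationTable(do.call(rbind, out), list(
      pixel_size_nm = cfg@pixel_size_nm, axial_range_nm = L[3],
      channels = cfg@channels@names,
      source = sprintf("simulated-beads(seed=%g)", cfg@seed),
      bead_truth = B))
  })
}
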