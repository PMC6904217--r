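#' Specification of a synthetic comparative dataset
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the structure of the study dataset: an ultrametric tree of 79
#' tips spanning 425 Myr; maximal retinal thickness evolving by Brownian
#' motion from an ancestral 194 um with a +100 um shift where the choroid
#' rete mirabile (CRM) is present; a Root effect trait elevated by the CRM;
#' binary vascular characters evolving under an equal-rates Mk process from
#' an "absent" root; log-scale eye-mass allometry with slope 0.77 and
#' intercept -2.64 on body mass; and retinal layers as fixed fractions of
#' the total thickness.
#'
#' @param seed Integer seed (mandatory; the generator is a pure function of
#'   this spec).
#' @param n_tips Number of species.
#' @param depth Tree depth (Myr).
#' @param traits Named list; per trait: `sigma2` (units^2/Myr), `z0`,
#'   optional `effect = list(char =, state =, delta =)` applied at
#'   state-transition points, optional `log10` flag to report 10^value.
#' @param discrete Named list; per character: `q` (per Myr), `states`,
#'   `root_state`.
#' @param allometry List `slope`, `intercept`, `noise_sd` (log10 units at
#'   the tips; the deviation itself evolves as BM), `body_sigma2`,
#'   `body_z0` (log10 g).
#' @param layer_fractions Named fractions of total thickness.
#' @param missingness Fraction of species set to `NA` per measured trait.
#' @return Object of class `"synth_spec"`.
#' @export
synth_spec <- function(seed,
                       n_tips = 79L,
                       depth = 425,
                       traits = list(
                         thickness_um = list(sigma2 = 34, z0 = 194,
                           effect = list(char = "crm", state = "present",
                                         delta = 100)),
                         root_effect_pct = list(sigma2 = 1.0, z0 = 5,
                           effect = list(char = "crm", state = "present",
                                         delta = 40)),
                         prc_mm3_mm2 = list(sigma2 = 0.0015, z0 = -1.3,
                           effect = list(char = "crm", state = "present",
                                         delta = -0.5), log10 = TRUE)
                       ),
                       discrete = list(
                         crm = list(q = 0.005,
                                    states = c("absent", "present"),
                                    root_state = "absent"),
                         intra_retinal = list(q = 0.003,
                                    states = c("absent", "present"),
                                    root_state = "absent"),
                         pre_retinal = list(q = 0.008,
                                    states = c("absent", "present"),
                                    root_state = "absent")
                       ),
                       allometry = list(slope = 0.77, intercept = -2.64,
                                        noise_sd = 0.1,
                                        body_sigma2 = 0.005, body_z0 = 1),
                       layer_fractions = c(PEPRL = 0.35, ONL = 0.15,
                                           OPL = 0.05, INL = 0.15,
                                           IPL = 0.18, GCL = 0.07,
                                           NFL = 0.05),
                       missingness = 0) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_tips >= 2L, depth > 0, missingness >= 0, missingness < 1)
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 depth = depth, traits = traits, discrete = discrete,
                 allometry = allometry, layer_fractions = layer_fractions,
                 missingness = missingness),
            class = "synth_spec")
}

#' Generate a pure-birth ultrametric tree
#'
#' A Yule tree conditioned on the requested tip count, rescaled so that the
#' root-to-tip depth equals `depth` exactly. Deterministic given the seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param depth Tree depth (Myr).
#' @param seed Integer seed.
#' @return A `"phylo"` tree with tip labels `sp01, sp02, ...`.
#' @export
generate_tree <- function(n_tips, depth = 425, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_tips >= 2L)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  d <- max(node_depths(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length * depth / d
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

# Forward simulation of an ER Mk character, recording the full history.
.simulate_mk_forward <- function(tree, q, k, root_state) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  ns <- integer(nn)
  ns[ntip + 1L] <- root_state
  segs <- vector("list", nrow(po$edge))
  for (e in pre) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    path <- .forward_path(ns[p], po$edge.length[e], k, q)
    ns[ch] <- if (length(path$states)) path$states[length(path$states)] else ns[p]
    if (length(path$states)) segs[[e]] <- path
  }
  list(node_states = ns, segments = segs, edge = po$edge)
}

# Net count of entries-minus-exits of `state` along each edge history.
.net_shift <- function(sim, e, state) {
  sg <- sim$segments[[e]]
  if (is.null(sg)) return(0L)
  prev <- c(sim$node_states[sim$edge[e, 1L]], sg$states[-length(sg$states)])
  sum(sg$states == state) - sum(prev == state & sg$states != state)
}

#' Generate a synthetic trait table with known ground truth
#'
#' Simulates, on one tree: binary (or multistate) characters forward under
#' the equal-rates Mk process; continuous traits under Brownian motion with
#' additive mean shifts applied at the character's state-transition points
#' (so a trait is shifted by `delta` while the lineage carries the focal
#' state); body mass as BM on the log10 scale and eye mass from the
#' allometric model with a phylogenetic (BM) deviation; and retinal layers
#' as fixed fractions of the total thickness. All internal-node truths and
#' parameters are returned for recovery tests.
#'
#' @param spec A [synth_spec()].
#' @return List: `tree`, `traits` (data frame, one row per species),
#'   `truth` (node states/values, histories, spec).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  tree <- generate_tree(spec$n_tips, spec$depth, spec$seed)
  set.seed(spec$seed + 1L)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))

  chars <- list()
  for (nm in names(spec$discrete)) {
    dc <- spec$discrete[[nm]]
    k <- length(dc$states)
    sim <- .simulate_mk_forward(tree, dc$q, k, match(dc$root_state, dc$states))
    chars[[nm]] <- sim
  }

  trait_vals <- list()
  for (nm in names(spec$traits)) {
    tp <- spec$traits[[nm]]
    vals <- numeric(nn)
    vals[ntip + 1L] <- tp$z0
    eff <- tp$effect
    for (e in pre) {
      p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      inc <- stats::rnorm(1L, 0, sqrt(tp$sigma2 * po$edge.length[e]))
      shift <- 0
      if (!is.null(eff)) {
        sim <- chars[[eff$char]]
        st <- match(eff$state, spec$discrete[[eff$char]]$states)
        shift <- eff$delta * .net_shift(sim, e, st)
      }
      vals[ch] <- vals[p] + inc + shift
    }
    trait_vals[[nm]] <- vals
  }

  al <- spec$allometry
  body <- .simulate_bm_raw(tree, al$body_sigma2, al$body_z0, 1L)[, 1L]
  dev <- .simulate_bm_raw(tree, al$noise_sd^2 / spec$depth, 0, 1L)[, 1L]
  eye <- al$intercept + al$slope * body + dev

  tipv <- function(v) v[seq_len(ntip)]
  traits <- data.frame(species = tree$tip.label,
                       body_mass_g = 10^tipv(body),
                       eye_mass_g = 10^tipv(eye))
  for (nm in names(spec$traits)) {
    v <- tipv(trait_vals[[nm]])
    if (isTRUE(spec$traits[[nm]]$log10)) v <- 10^v
    traits[[nm]] <- v
  }
  if ("thickness_um" %in% names(traits)) {
    for (ly in names(spec$layer_fractions)) {
      traits[[ly]] <- traits$thickness_um * spec$layer_fractions[[ly]]
    }
  }
  for (nm in names(chars)) {
    st <- spec$discrete[[nm]]$states
    traits[[nm]] <- st[chars[[nm]]$node_states[seq_len(ntip)]]
  }
  if (spec$missingness > 0) {
    measured <- setdiff(names(traits), c("species", "body_mass_g",
                                         "eye_mass_g", names(chars)))
    for (nm in measured) {
      drop <- stats::runif(ntip) < spec$missingness
      traits[[nm]][drop] <- NA
    }
  }
  rownames(traits) <- traits$species
  truth <- list(
    node_states = lapply(chars, function(s) s$node_states),
    histories = chars,
    node_values = trait_vals,
    body_log10 = body, eye_log10 = eye,
    spec = spec
  )
  list(tree = tree, traits = traits, truth = truth)
}

#' Generate an ocular geometry phantom with voxelization
#'
#' Draws a random valid [eye_geometry()] and voxelizes the eye sphere on a
#' cubic grid, together with a systematic section/point-grid sample for the
#' Cavalieri estimator. Reproducible given the seed.
#'
#' @param seed Integer seed.
#' @param res Voxels per axis across the eye diameter.
#' @param section_every Take every k-th voxel plane as a Cavalieri section.
#' @param grid_every Point-grid spacing in voxels within each section.
#' @param r_eye Optional fixed eye radius (mm); random in \[1.5, 3\] if
#'   `NULL`.
#' @return List: `geometry`, `voxel_size` (mm), `mask_eye` (logical array),
#'   `stereology` (spacing, `a_p`, `point_hits` per section).
#' @export
generate_eye_phantom <- function(seed, res = 120L, section_every = 8L,
                                 grid_every = 4L, r_eye = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  if (is.null(r_eye)) r_eye <- stats::runif(1L, 1.5, 3)
  r_retina <- r_eye * stats::runif(1L, 0.75, 0.92)
  d_er <- (r_eye - r_retina) * stats::runif(1L, 1.0, 1.5)
  r_crm <- r_eye * stats::runif(1L, 0.3, 0.5)
  d_ec <- stats::runif(1L, r_eye * 0.9, r_eye + 0.3 * r_crm)
  r_no <- r_crm * stats::runif(1L, 0.1, 0.25)
  d_cn <- r_crm * stats::runif(1L, 0.5, 0.9)
  g <- eye_geometry(r_eye, r_retina, d_er, r_crm, r_no, d_ec, d_cn)
  h <- 2 * r_eye / res
  ax <- (seq_len(res) - 0.5) * h - r_eye
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  mask <- r2 <= r_eye^2
  zsec <- seq(1L, res, by = section_every)
  a_p <- (grid_every * h)^2
  gx <- seq(1L, res, by = grid_every)
  hits <- vapply(zsec, function(z) sum(mask[gx, gx, z]), 0L)
  list(geometry = g, voxel_size = h, mask_eye = mask,
       stereology = list(spacing = section_every * h, a_p = a_p,
                         point_hits = hits))
}

#' Generate a synthetic speckle image stack with known vessel mask
#'
#' Static tissue pixels fluctuate with small iid noise around a constant
#' baseline; vessel pixels fluctuate with `contrast`-fold larger temporal
#' standard deviation, emulating dynamic blood speckle. The vessel mask is
#' returned as ground truth for separation checks on [quadratic_average()].
#'
#' @param seed Integer seed.
#' @param nx,ny Image size (pixels).
#' @param n_frames Temporal frames (N >= 2).
#' @param vessel_frac Fraction of pixels belonging to vessels.
#' @param baseline Mean intensity.
#' @param tissue_sd Temporal SD of tissue pixels (0 for noise-free tissue).
#' @param contrast Vessel-to-tissue temporal SD ratio.
#' @param vessel_sd Absolute vessel temporal SD; default
#'   `contrast * tissue_sd`.
#' @return List: `stack` (nx x ny x n_frames array), `mask` (logical
#'   nx x ny), parameters.
#' @export
generate_speckle_stack <- function(seed, nx = 48L, ny = 48L, n_frames = 64L,
                                   vessel_frac = 0.15, baseline = 100,
                                   tissue_sd = 1, contrast = 10,
                                   vessel_sd = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_frames >= 2L)
  if (is.null(vessel_sd)) vessel_sd <- contrast * tissue_sd
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(nx * ny) < vessel_frac, nx, ny)
  sds <- ifelse(mask, vessel_sd, tissue_sd)
  stack <- array(stats::rnorm(nx * ny * n_frames, baseline, rep(sds, n_frames)),
                 dim = c(nx, ny, n_frames))
  list(stack = stack, mask = mask,
       params = list(vessel_frac = vessel_frac, baseline = baseline,
                     tissue_sd = tissue_sd, contrast = contrast))
}
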