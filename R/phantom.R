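## Region label dictionary shared across the package.
REGION_LEVELS <- c(background = 0L, brain = 1L, corpus_callosum = 2L,
                   tumor_core = 3L, needle_tract = 4L, contralateral = 5L)

## priority when region geometries overlap (higher wins)
REGION_PRIORITY <- c(brain = 1, contralateral = 2, needle_tract = 3,
                     corpus_callosum = 4, tumor_core = 5)

#' Region label dictionary
#'
#' Integer codes used in phantom label volumes and mask files.
#'
#' @return named integer vector mapping region name to label code.
#' @export
region_labels <- function() REGION_LEVELS

## build a symmetric 3x3 tensor from eigenvalues and a principal axis;
## the two minor eigenvalues share the plane orthogonal to `axis`.
tensor_from_eigen <- function(eigenvalues, axis = c(1, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  ## complete an orthonormal frame
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * axis) * axis
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(axis[2] * e2[3] - axis[3] * e2[2],
          axis[3] * e2[1] - axis[1] * e2[3],
          axis[1] * e2[2] - axis[2] * e2[1])
  v <- cbind(axis, e2, e3)
  v %*% diag(eigenvalues) %*% t(v)
}

## default tissue parameter sets: storage/loss modulus (Pa), T2 (msec),
## diffusion eigenvalues (mm^2/s) and principal axis
default_region_params <- function() {
  list(
    brain = list(gd = 5000, gl = 2000, t2 = 40.4,
                 eigenvalues = c(0.80, 0.55, 0.55) * 1e-3, axis = c(1, 0, 0)),
    corpus_callosum = list(gd = 4440, gl = 1640, t2 = 40.5,
                           eigenvalues = c(1.25, 0.35, 0.35) * 1e-3,
                           axis = c(1, 0, 0)),
    tumor_core = list(gd = 3600, gl = 1500, t2 = 40.19,
                      eigenvalues = c(0.72, 0.54, 0.54) * 1e-3,
                      axis = c(1, 0, 0)),
    needle_tract = list(gd = 5000, gl = 2000, t2 = 40.4,
                        eigenvalues = c(0.80, 0.55, 0.55) * 1e-3,
                        axis = c(0, 1, 0)),
    contralateral = list(gd = 5000, gl = 2000, t2 = 40.4,
                         eigenvalues = c(0.80, 0.55, 0.55) * 1e-3,
                         axis = c(1, 0, 0))
  )
}

## voxelize one region geometry -> logical mask
region_mask <- function(geom, grid_shape, spacing) {
  co <- grid_coords(grid_shape, spacing)
  X <- array(co[[1]], grid_shape)
  Y <- aperm(array(co[[2]], grid_shape[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(co[[3]], grid_shape[c(3, 1, 2)]), c(2, 3, 1))
  if (geom$shape == "ellipsoid") {
    c0 <- geom$center_mm
    r <- geom$radii_mm
    ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 + ((Z - c0[3]) / r[3])^2 <= 1
  } else if (geom$shape == "band") {
    ## axis-aligned curved band: thickness about a curved midline
    ## y0(x) = center_mm[2] + curvature * (x - center_mm[1])^2
    y0 <- geom$center_mm[2] + (geom$curvature %||% 0) * (X - geom$center_mm[1])^2
    abs(Y - y0) <= geom$half_thickness_mm &
      abs(X - geom$center_mm[1]) <= geom$half_length_mm &
      abs(Z - geom$center_mm[3]) <= (geom$half_depth_mm %||% Inf)
  } else if (geom$shape == "cylinder") {
    ## needle tract: thin cylinder along z
    sqrt((X - geom$center_mm[1])^2 + (Y - geom$center_mm[2])^2) <= geom$radius_mm
  } else stop("unknown region shape: ", geom$shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## pick the ellipsoid radii scale so the voxelized volume matches a target
## within one voxel volume: each voxel centre enters the ellipsoid at a
## unique scale (its normalized radius), so placing the scale between the
## k-th and (k+1)-th order statistic captures exactly k voxels
calibrate_volume <- function(geom, grid_shape, spacing, target_mm3) {
  vox <- prod(spacing)
  base_r <- geom$radii_mm / (prod(geom$radii_mm))^(1 / 3)  # unit-volume shape
  co <- grid_coords(grid_shape, spacing)
  X <- array(co[[1]], grid_shape)
  Y <- aperm(array(co[[2]], grid_shape[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(co[[3]], grid_shape[c(3, 1, 2)]), c(2, 3, 1))
  rho <- sqrt(((X - geom$center_mm[1]) / base_r[1])^2 +
                ((Y - geom$center_mm[2]) / base_r[2])^2 +
                ((Z - geom$center_mm[3]) / base_r[3])^2)
  k <- max(1L, round(target_mm3 / vox))
  rho_sorted <- sort(as.vector(rho), partial = min(k + 1, length(rho)))
  if (k >= length(rho)) {
    warning("requested volume exceeds the grid; using all voxels")
    s <- max(rho) + 1
  } else if (rho_sorted[k] == rho_sorted[k + 1]) {
    warning("voxel entry-scale tie; volume may be off by the tied voxels")
    s <- rho_sorted[k]
  } else {
    s <- (rho_sorted[k] + rho_sorted[k + 1]) / 2
  }
  if (abs(k * vox - target_mm3) > vox)
    warning("voxelized volume off target by more than one voxel volume")
  geom$radii_mm <- base_r * s
  geom
}

#' Build a voxelized tissue-property phantom
#'
#' Creates per-voxel maps of the viscoelastic moduli (storage `gd`, loss
#' `gl`, Pa), T2 relaxation time (msec), symmetric diffusion tensors
#' (mm^2/s) and integer region labels on a regular grid. The default
#' geometry is a 64 x 64 in-plane matrix with 9 slices at 0.3 mm isotropic
#' spacing (a 19.2 x 19.2 mm field of view), matching a small-animal
#' multi-slice multi-echo elastography protocol.
#'
#' Regions are voxelized in priority order (tumor core over corpus callosum
#' over needle tract over brain), so overlapping geometries resolve to the
#' highest-priority region. An ellipsoidal region may specify `volume_mm3`
#' instead of fixed radii, in which case its radii are rescaled so that the
#' labeled voxel count times the voxel volume matches the target within one
#' voxel volume.
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param spacing numeric 3-vector, mm per voxel.
#' @param regions named list: for each region (`brain` required), a list
#'   with tissue parameters `gd`, `gl` (Pa), `t2` (msec), `eigenvalues`
#'   (diffusion eigenvalues, mm^2/s), optional `axis` (principal diffusion
#'   direction), and for non-brain regions a geometry (`shape` one of
#'   `"ellipsoid"`, `"band"`, `"cylinder"` plus its parameters). `brain`
#'   itself may carry an ellipsoid geometry; by default it fills an
#'   ellipsoid inscribed in the grid.
#' @param density tissue density, kg/m^3 (single global value).
#' @return an object of class `property_phantom`: list with `grid_shape`,
#'   `spacing`, `gd`, `gl`, `t2`, `density`, `tensors` (4-D array, 6 unique
#'   components Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `labels` and `regions`.
#' @export
build_property_phantom <- function(grid_shape = c(64, 64, 9),
                                   spacing = c(0.3, 0.3, 0.3),
                                   regions = list(),
                                   density = 1000) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, length(spacing) == 3, all(spacing > 0))
  defaults <- default_region_params()
  for (nm in names(regions))
    if (!nm %in% names(REGION_LEVELS) || nm == "background")
      stop("unknown region: ", nm)
  ## merge parameter defaults
  reg <- list()
  for (nm in union("brain", names(regions))) {
    p <- defaults[[nm]]
    for (f in names(regions[[nm]])) p[[f]] <- regions[[nm]][[f]]
    reg[[nm]] <- p
  }
  for (nm in names(reg)) {
    if (!is.null(reg[[nm]]$gd) && reg[[nm]]$gd <= 0)
      stop("storage modulus must be positive in region ", nm)
    if (!is.null(reg[[nm]]$gl) && reg[[nm]]$gl < 0)
      stop("loss modulus must be non-negative in region ", nm)
  }
  ## default brain geometry: ellipsoid inscribed in the in-plane FOV,
  ## spanning all slices
  fov <- grid_shape * spacing
  if (is.null(reg$brain$shape)) {
    reg$brain$shape <- "ellipsoid"
    reg$brain$center_mm <- (grid_shape - 1) / 2 * spacing
    reg$brain$radii_mm <- c(fov[1] * 0.47, fov[2] * 0.47, fov[3])
  }

  lab <- array(REGION_LEVELS[["background"]], grid_shape)
  nms <- names(reg)[order(REGION_PRIORITY[names(reg)])]
  for (nm in nms) {
    g <- reg[[nm]]
    if (is.null(g$shape)) stop("region ", nm, " has no geometry")
    if (!is.null(g$volume_mm3) && g$shape == "ellipsoid") {
      if (is.null(g$radii_mm)) g$radii_mm <- c(1, 1, 1)
      g <- calibrate_volume(g, grid_shape, spacing, g$volume_mm3)
      reg[[nm]] <- g
    }
    m <- region_mask(g, grid_shape, spacing)
    if (nm != "brain" && !any(m & lab != 0))
      stop("region ", nm, " lies outside the brain/grid")
    lab[m] <- REGION_LEVELS[[nm]]
  }

  gd <- array(0, grid_shape)
  gl <- array(0, grid_shape)
  t2 <- array(0, grid_shape)
  tens <- array(0, c(grid_shape, 6))
  for (nm in names(reg)) {
    m <- lab == REGION_LEVELS[[nm]]
    if (!any(m)) next
    p <- reg[[nm]]
    gd[m] <- p$gd
    gl[m] <- p$gl
    t2[m] <- p$t2
    D <- tensor_from_eigen(p$eigenvalues, p$axis %||% c(1, 0, 0))
    comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    for (k in 1:6) {
      slab <- tens[, , , k]
      slab[m] <- comp[k]
      tens[, , , k] <- slab
    }
  }
  structure(list(grid_shape = grid_shape, spacing = spacing, gd = gd,
                 gl = gl, t2 = t2, density = density, tensors = tens,
                 labels = lab, regions = reg),
            class = "property_phantom")
}

#' @export
print.property_phantom <- function(x, ...) {
  cat("Property phantom:", paste(x$grid_shape, collapse = " x "),
      "voxels at", paste(sprintf("%g", x$spacing), collapse = " x "),
      "mm\n")
  tab <- table(factor(x$labels, levels = REGION_LEVELS,
                      labels = names(REGION_LEVELS)))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("  %-16s %6d voxels (%.2f mm^3)\n", nm, tab[[nm]],
                tab[[nm]] * prod(x$spacing)))
  invisible(x)
}

#' Synthesize a multi-echo T2 decay train
#'
#' Forward model: mono-exponential decay `s0 * exp(-TE / T2)` per voxel,
#' with optional magnitude (Rician-style) noise formed as the modulus of
#' two independent Gaussian channels of standard deviation `noise_sd`.
#' With `noise_sd = 0` the exact decay is returned. Voxels with
#' non-positive T2 (background) emit zero signal and are flagged.
#'
#' @param phantom a `property_phantom`.
#' @param te_list echo times, msec; default 7 to 210 msec in 7 msec steps
#'   (30 echoes).
#' @param s0 proton-density amplitude (arbitrary units), positive.
#' @param noise_sd Gaussian channel noise SD (same units as `s0`).
#' @param seed integer seed for the noise draw.
#' @return class `echo_train`: list with `te` (msec), `signal` (4-D array,
#'   last axis echo), `noise_sd`, `zero_t2` flag mask and `spacing`.
#' @export
synthesize_echo_train <- function(phantom, te_list = seq(7, 210, by = 7),
                                  s0 = 1000, noise_sd = 0, seed = 1) {
  stopifnot(length(te_list) >= 1, s0 > 0, noise_sd >= 0)
  if (any(diff(te_list) <= 0)) stop("te_list must be strictly increasing")
  dm <- phantom$grid_shape
  ne <- length(te_list)
  t2 <- phantom$t2
  bad <- t2 <= 0
  t2s <- ifelse(bad, Inf, t2)
  sig <- array(0, c(dm, ne))
  for (k in seq_len(ne)) {
    s <- s0 * exp(-te_list[k] / t2s)
    s[bad] <- 0
    sig[, , , k] <- s
  }
  if (noise_sd > 0) {
    sig <- with_seed(seed, {
      n <- length(sig)
      sqrt((sig + rnorm(n, sd = noise_sd))^2 + rnorm(n, sd = noise_sd)^2)
    })
    dim(sig) <- c(dm, ne)
  }
  structure(list(te = te_list, signal = sig, noise_sd = noise_sd,
                 zero_t2 = bad, spacing = phantom$spacing),
            class = "echo_train")
}

#' Default 30-direction diffusion gradient scheme
#'
#' A fixed set of 30 unit vectors spread by antipodal electrostatic
#' repulsion (Coulomb energy minimization over sign-symmetric pairs), the
#' standard construction for well-conditioned diffusion tensor sampling.
#'
#' @return a 30 x 3 matrix of unit row vectors.
#' @export
dti_directions_30 <- function() {
  m <- matrix(c(
    0.879135636, 0.433773820, -0.197384918,
    -0.404607842, 0.867120662, 0.290506887,
    0.457413105, 0.740802170, 0.491920113,
    0.595914117, -0.214654042, 0.773828151,
    0.251288980, 0.207343983, -0.945442923,
    0.138472982, -0.796733899, 0.588251925,
    0.862709856, -0.352000941, 0.363079939,
    0.186492056, -0.428838129, 0.883922266,
    0.550984226, -0.643340264, 0.531535218,
    0.242391083, 0.035021012, 0.969546333,
    0.660785894, 0.304678951, -0.685953890,
    0.931679936, -0.349914976, -0.097631993,
    -0.723751000, 0.524199000, 0.448776000,
    -0.158961015, -0.519660049, -0.839455079,
    0.003752000, -0.839862007, -0.542787004,
    0.569307073, 0.334717043, 0.750902096,
    -0.263628908, -0.617743783, 0.740872740,
    -0.687414793, 0.723520782, -0.063075981,
    -0.852863003, -0.088412000, -0.514595002,
    0.591353963, 0.689785957, -0.417726974,
    -0.188967023, 0.231918028, 0.954204115,
    -0.814677397, -0.503407245, -0.287892140,
    0.111647001, 0.983942009, 0.139259001,
    0.567692983, 0.822400976, 0.037165999,
    0.906178093, -0.005459001, -0.422861044,
    -0.359505232, 0.595634384, 0.718314463,
    -0.279585140, 0.946559475, -0.160802081,
    -0.994286098, -0.079880008, -0.070812007,
    -0.207639058, -0.929129259, 0.305949085,
    -0.619629926, 0.161339981, 0.768132909), ncol = 3, byrow = TRUE)
  m / sqrt(rowSums(m^2))
}

#' Synthesize a diffusion-weighted acquisition
#'
#' Forward model per voxel and gradient direction `g`:
#' `S = s0 * exp(-b * g' D g)` from the phantom's diffusion tensors, with
#' one unweighted (b = 0) reference volume first, plus optional two-channel
#' magnitude noise. The default scheme is b = 1500 s/mm^2 over 30
#' repulsion-optimized directions.
#'
#' @param phantom a `property_phantom`.
#' @param bvalue diffusion weighting of the weighted volumes, s/mm^2.
#' @param directions n x 3 matrix of unit gradient vectors.
#' @param s0 unweighted signal amplitude.
#' @param noise_sd Gaussian channel noise SD.
#' @param seed integer seed.
#' @return class `dwi_set`: `bvalues` (length n+1, first 0), `directions`
#'   ((n+1) x 3, first row zero), `signal` (4-D array, last axis volume),
#'   `noise_sd`, `spacing`.
#' @export
synthesize_dwi <- function(phantom, bvalue = 1500,
                           directions = dti_directions_30(),
                           s0 = 1000, noise_sd = 0, seed = 1) {
  if (bvalue < 0) stop("b-value must be non-negative")
  directions <- as.matrix(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("gradient directions must be unit-norm")
  dm <- phantom$grid_shape
  nd <- nrow(directions)
  sig <- array(0, c(dm, nd + 1))
  sig[, , , 1] <- s0
  tn <- phantom$tensors
  for (k in seq_len(nd)) {
    g <- directions[k, ]
    ## g' D g for symmetric D with unique components
    q <- tn[, , , 1] * g[1]^2 + tn[, , , 2] * g[2]^2 + tn[, , , 3] * g[3]^2 +
      2 * (tn[, , , 4] * g[1] * g[2] + tn[, , , 5] * g[1] * g[3] +
             tn[, , , 6] * g[2] * g[3])
    sig[, , , k + 1] <- s0 * exp(-bvalue * q)
  }
  if (noise_sd > 0) {
    sig <- with_seed(seed, {
      n <- length(sig)
      sqrt((sig + rnorm(n, sd = noise_sd))^2 + rnorm(n, sd = noise_sd)^2)
    })
    dim(sig) <- c(dm, nd + 1)
  }
  structure(list(bvalues = c(0, rep(bvalue, nd)),
                 directions = rbind(0, directions),
                 signal = sig, noise_sd = noise_sd, spacing = phantom$spacing),
            class = "dwi_set")
}
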