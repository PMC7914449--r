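# Trajectory analysis on grouped coordinates in a rectangular periodic box:
# recentring on a reference group, per-group mass density profiles along the
# bilayer normal, contact counts within a cutoff under the minimum-image
# convention, and concordance between density overlap and NOESY rankings.

wrap_z <- function(z, Lz) ((z + Lz / 2) %% Lz) - Lz / 2

#' Centre trajectory frames on a reference group
#'
#' Shifts z per frame so the reference group's centre of mass sits at z = 0
#' (the conventional bilayer-centre origin when the reference is the
#' terminal methyls); x, y are untouched and z is re-wrapped into
#' [-Lz/2, Lz/2).
#'
#' @param t a [group_trajectory()].
#' @param reference_group group label present in every frame.
#' @return recentred [group_trajectory()].
#' @export
center_frames <- function(t, reference_group) {
  stopifnot(inherits(t, "group_trajectory"))
  Lz <- t$box[3]
  frames <- lapply(seq_along(t$frames), function(i) {
    f <- t$frames[[i]]
    ref <- f$group == reference_group
    if (!any(ref))
      stop(sprintf("reference group '%s' missing in frame %d",
                   reference_group, i))
    com <- sum(f$z[ref] * f$mass[ref]) / sum(f$mass[ref])
    f$z <- wrap_z(f$z - com, Lz)
    f
  })
  group_trajectory(frames, t$box)
}

DA_PER_NM3_TO_KG_M3 <- 1.66053906660  # 1 Da/nm^3 in kg/m^3

#' Per-group mass density profile along the bilayer normal
#'
#' Histograms each group's mass into uniform z bins spanning [-Lz/2, Lz/2],
#' divides by the bin volume Lx * Ly * bin_width, averages over frames and
#' converts Da/nm^3 to kg/m^3. The requested bin width is adjusted to the
#' nearest width that tiles the box exactly, so the profile conserves group
#' mass exactly: sum(density) * bin_volume = group mass per frame.
#'
#' @param t a centred [group_trajectory()].
#' @param groups group labels to profile (default: all present).
#' @param bin_width requested bin width (nm), > 0 (default 0.1).
#' @return object of class `density_profile`: list with `z` (bin centres,
#'   nm), `density` (matrix bin x group, kg/m^3), `bin_width` (nm, as
#'   used), `box`.
#' @export
mass_density_profile <- function(t, groups = NULL, bin_width = 0.1) {
  stopifnot(inherits(t, "group_trajectory"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  box <- t$box
  if (box[1] * box[2] <= 0) stop("zero box cross-section area")
  Lz <- box[3]
  n_bins <- max(1L, round(Lz / bin_width))
  w <- Lz / n_bins
  edges <- seq(-Lz / 2, Lz / 2, length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  if (is.null(groups)) groups <- unique(t$frames[[1]]$group)
  dens <- matrix(0, n_bins, length(groups), dimnames = list(NULL, groups))
  n_frames <- length(t$frames)
  for (f in t$frames) {
    z <- wrap_z(f$z, Lz)
    bin <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L),
                n_bins)
    for (g in groups) {
      sel <- f$group == g
      if (!any(sel)) next
      m <- tapply(f$mass[sel], factor(bin[sel], levels = seq_len(n_bins)),
                  sum)
      m[is.na(m)] <- 0
      dens[, g] <- dens[, g] + as.numeric(m)
    }
  }
  vol <- box[1] * box[2] * w                 # nm^3
  dens <- dens / (n_frames * vol) * DA_PER_NM3_TO_KG_M3
  structure(list(z = centers, density = dens, bin_width = w, box = box,
                 n_frames = n_frames),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d bins (%.3f nm), groups: %s\n",
              length(x$z), x$bin_width,
              paste(colnames(x$density), collapse = ", ")))
  invisible(x)
}

min_image <- function(d, L) d - L * round(d / L)

#' Count inter-group atom contacts within a cutoff
#'
#' Per frame, the number of atom pairs (a in A, b in B) whose
#' minimum-image distance is below the cutoff; the mean over frames is
#' reported. Symmetric in (A, B) by construction.
#'
#' @param t a [group_trajectory()].
#' @param groupA,groupB distinct group labels (overlapping atom sets, i.e.
#'   `groupA == groupB`, are an error).
#' @param cutoff contact distance (nm), > 0 (default 0.5, wide enough to
#'   include most interaction types).
#' @return object of class `contact_counts`: list `pair`, `cutoff`,
#'   `mean_contacts`, `per_frame`, `n_frames`.
#' @export
count_contacts <- function(t, groupA, groupB, cutoff = 0.5) {
  stopifnot(inherits(t, "group_trajectory"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (identical(groupA, groupB))
    stop("groups must be disjoint atom sets (groupA == groupB)")
  box <- t$box
  per_frame <- vapply(t$frames, function(f) {
    A <- f[f$group == groupA, c("x", "y", "z")]
    B <- f[f$group == groupB, c("x", "y", "z")]
    if (nrow(A) == 0L || nrow(B) == 0L) return(0)
    dx <- min_image(outer(A$x, B$x, "-"), box[1])
    dy <- min_image(outer(A$y, B$y, "-"), box[2])
    dz <- min_image(outer(A$z, B$z, "-"), box[3])
    sum(dx * dx + dy * dy + dz * dz < cutoff^2)
  }, numeric(1))
  structure(list(pair = c(groupA, groupB), cutoff = cutoff,
                 mean_contacts = mean(per_frame), per_frame = per_frame,
                 n_frames = length(per_frame)),
            class = "contact_counts")
}

#' @export
print.contact_counts <- function(x, ...) {
  cat(sprintf("<contact_counts> %s-%s within %.2f nm: %.2f per frame (%d frames)\n",
              x$pair[1], x$pair[2], x$cutoff, x$mean_contacts, x$n_frames))
  invisible(x)
}

# Overlap of two unit-normalised histograms on a shared grid: integral of
# the pointwise minimum (1 = identical, 0 = disjoint).
profile_overlap <- function(z, a, b, w) {
  ia <- sum(a) * w; ib <- sum(b) * w
  if (ia <= 0 || ib <= 0) return(0)
  sum(pmin(a / ia, b / ib)) * w
}

#' Concordance between density-profile overlap and NOESY rankings
#'
#' For each ligand group shared between a density profile and a
#' cross-relaxation profile, ranks the lipid groups by (i) the overlap
#' integral of unit-normalised density profiles with the ligand and (ii)
#' the NOESY cross-relaxation rate, and reports the Spearman rank
#' correlation between the two orderings.
#'
#' @param dp a `density_profile` containing both lipid and ligand group
#'   columns.
#' @param cp a `cross_relaxation_profile`.
#' @return list keyed by ligand group: `rho` (Spearman), `n_groups`,
#'   `overlap` (named), `sigma` (named); attribute
#'   `insufficient_data` when fewer than 3 lipid groups are shared.
#' @export
profile_noesy_concordance <- function(dp, cp) {
  stopifnot(inherits(dp, "density_profile"),
            inherits(cp, "cross_relaxation_profile"))
  lipid <- intersect(rownames(cp$rates), colnames(dp$density))
  ligands <- intersect(colnames(cp$rates), colnames(dp$density))
  out <- list()
  insufficient <- length(lipid) < 3L
  for (lig in ligands) {
    ov <- vapply(lipid, function(g)
      profile_overlap(dp$z, dp$density[, lig], dp$density[, g],
                      dp$bin_width), numeric(1))
    sg <- cp$rates[lipid, lig]
    rho <- if (insufficient) NA_real_ else
      stats::cor(rank(ov), rank(sg), method = "spearman")
    out[[lig]] <- list(rho = rho, n_groups = length(lipid),
                       overlap = ov, sigma = sg)
  }
  attr(out, "insufficient_data") <- insufficient
  out
}
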