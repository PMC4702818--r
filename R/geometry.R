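# Vector geometry helpers (degrees). Points are length-3 numerics or
# n-by-3 matrices (row-wise).

vec_angle <- function(a, b, c) {
  u <- a - b; w <- c - b
  if (is.null(dim(u))) { u <- rbind(u); w <- rbind(w) }
  cosang <- rowSums(u * w) / (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

vec_dihedral <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)   # range (-180, 180]
}

# consecutive trace-atom pairs of one chain: rows i, i+1 with resno
# difference exactly 1 (numbering gaps denote unmodeled residues and are
# skipped, not flagged)
consecutive_pairs <- function(tr) {
  if (is.null(tr) || nrow(tr) < 2L) return(integer(0))
  which(diff(tr$resno) == 1L)
}

#' Consecutive C-alpha--C-alpha distance outliers
#'
#' Evaluates every pair of sequence-consecutive residues (residue numbers
#' differing by exactly 1; numbering gaps are skipped) of each protein
#' chain, using their CA atoms. A distance is an outlier when it falls
#' outside the mean +/- `sigma_multiplier` * sigma window of the cis
#' distribution AND outside the corresponding window of the trans
#' distribution; a distance acceptable under either peptide isomer is not
#' flagged. The nearest class (smaller absolute z-score) is recorded.
#'
#' @param model an [atom_model].
#' @param ref a [reference_distributions] object supplying the cis/trans
#'   means and sigmas.
#' @param sigma_multiplier width of the acceptance windows in sigmas
#'   (default 3).
#' @return A data frame with one row per evaluated pair: `chain`,
#'   `resno_a`, `resno_b`, `distance` (A), `z_cis`, `z_trans`,
#'   `nearest_class`, `deviation_sigma` (absolute z of the nearest class)
#'   and `outlier`.
#' @export
caca_distance_outliers <- function(model, ref = default_reference_distributions(),
                                   sigma_multiplier = 3) {
  stopifnot(inherits(model, "atom_model"),
            inherits(ref, "reference_distributions"))
  empty <- data.frame(chain = character(), resno_a = integer(),
                      resno_b = integer(), distance = numeric(),
                      z_cis = numeric(), z_trans = numeric(),
                      nearest_class = character(),
                      deviation_sigma = numeric(), outlier = logical(),
                      stringsAsFactors = FALSE)
  chains <- names(model$chain_types)[model$chain_types == "protein"]
  rows <- lapply(chains, function(ch) {
    tr <- chain_trace_atoms(model, ch, "CA")
    idx <- consecutive_pairs(tr)
    if (length(idx) == 0L) return(NULL)
    p <- as.matrix(tr[idx, c("x", "y", "z")])
    q <- as.matrix(tr[idx + 1L, c("x", "y", "z")])
    d <- sqrt(rowSums((p - q)^2))
    z_cis <- (d - ref$caca_cis["mean"]) / ref$caca_cis["sigma"]
    z_trans <- (d - ref$caca_trans["mean"]) / ref$caca_trans["sigma"]
    nearest <- ifelse(abs(z_cis) < abs(z_trans), "cis", "trans")
    data.frame(chain = ch, resno_a = tr$resno[idx],
               resno_b = tr$resno[idx + 1L], distance = d,
               z_cis = as.numeric(z_cis), z_trans = as.numeric(z_trans),
               nearest_class = nearest,
               deviation_sigma = pmin(abs(z_cis), abs(z_trans)),
               outlier = abs(z_cis) > sigma_multiplier &
                 abs(z_trans) > sigma_multiplier,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  out
}

#' Consecutive P--P distance outliers
#'
#' Evaluates sequence-consecutive P--P distances of each nucleic acid chain.
#' A distance is an outlier when strictly shorter than `short` or strictly
#' longer than `long` Angstrom; values exactly at a bound are acceptable.
#'
#' @param model an [atom_model].
#' @param ref optional [reference_distributions]; supplies the bounds unless
#'   overridden.
#' @param short,long distance bounds in Angstrom (defaults 4.4 and 8.0).
#' @return A data frame with one row per evaluated pair: `chain`,
#'   `resno_a`, `resno_b`, `distance`, `reason` (`"short"`, `"long"` or
#'   `NA`) and `outlier`.
#' @export
pp_distance_outliers <- function(model, ref = NULL, short = NULL, long = NULL) {
  stopifnot(inherits(model, "atom_model"))
  if (is.null(short)) short <- if (!is.null(ref)) ref$pp_short else 4.4
  if (is.null(long)) long <- if (!is.null(ref)) ref$pp_long else 8.0
  empty <- data.frame(chain = character(), resno_a = integer(),
                      resno_b = integer(), distance = numeric(),
                      reason = character(), outlier = logical(),
                      stringsAsFactors = FALSE)
  chains <- names(model$chain_types)[model$chain_types == "nucleic"]
  rows <- lapply(chains, function(ch) {
    tr <- chain_trace_atoms(model, ch, "P")
    idx <- consecutive_pairs(tr)
    if (length(idx) == 0L) return(NULL)
    p <- as.matrix(tr[idx, c("x", "y", "z")])
    q <- as.matrix(tr[idx + 1L, c("x", "y", "z")])
    d <- sqrt(rowSums((p - q)^2))
    reason <- ifelse(d < short, "short", ifelse(d > long, "long", NA))
    data.frame(chain = ch, resno_a = tr$resno[idx],
               resno_b = tr$resno[idx + 1L], distance = d,
               reason = reason, outlier = !is.na(reason),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  out
}

# (theta, eta) pairs for every scorable residue of every protein chain;
# used both by the outlier check and by reference-grid construction
trace_pseudo_geometry <- function(model) {
  empty <- data.frame(chain = character(), resno = integer(),
                      theta = numeric(), eta = numeric(),
                      stringsAsFactors = FALSE)
  chains <- names(model$chain_types)[model$chain_types == "protein"]
  rows <- lapply(chains, function(ch) {
    tr <- chain_trace_atoms(model, ch, "CA")
    if (is.null(tr) || nrow(tr) < 4L) return(NULL)
    # residue i scorable when i-1, i, i+1, i+2 are sequence-consecutive
    n <- nrow(tr)
    dr <- diff(tr$resno)
    ok <- which(dr[1:(n - 3L)] == 1L & dr[2:(n - 2L)] == 1L &
                  dr[3:(n - 1L)] == 1L)
    if (length(ok) == 0L) return(NULL)
    xyz <- as.matrix(tr[, c("x", "y", "z")])
    i <- ok + 1L   # the second residue of each window of four
    data.frame(chain = ch, resno = tr$resno[i],
               theta = vec_angle(xyz[i - 1L, , drop = FALSE],
                                 xyz[i, , drop = FALSE],
                                 xyz[i + 1L, , drop = FALSE]),
               eta = vec_dihedral(xyz[i - 1L, , drop = FALSE],
                                  xyz[i, , drop = FALSE],
                                  xyz[i + 1L, , drop = FALSE],
                                  xyz[i + 2L, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  out
}

#' Pseudo-Ramachandran analysis of C-alpha traces
#'
#' For each residue i whose neighbors i-1, i+1, i+2 are sequence-consecutive,
#' computes the pseudo-bond angle theta = angle(CA[i-1], CA[i], CA[i+1]) and
#' the pseudo-torsion eta = dihedral(CA[i-1], CA[i], CA[i+1], CA[i+2]), and
#' looks up the reference-grid frequency of the (theta, eta) bin. The
#' residue is an outlier when that frequency is strictly below the
#' reference cutoff. The window convention (angles assigned to the second
#' residue of each window of four) is recorded in the result's
#' `"convention"` attribute.
#'
#' @param model an [atom_model].
#' @param ref a [reference_distributions] with a non-`NULL` `rama` grid.
#' @return A data frame with one row per scored residue: `chain`, `resno`,
#'   `theta`, `eta`, `frequency` and `outlier`.
#' @export
pseudo_ramachandran <- function(model, ref = default_reference_distributions()) {
  stopifnot(inherits(model, "atom_model"))
  if (!inherits(ref, "reference_distributions") || is.null(ref$rama))
    stop("reference required: pseudo-Ramachandran analysis needs a reference grid")
  g <- trace_pseudo_geometry(model)
  rama <- ref$rama
  if (nrow(g) > 0) {
    ti <- rama_bin_theta(g$theta, rama$bin_width, nrow(rama$freq))
    ei <- rama_bin_eta(g$eta, rama$bin_width, ncol(rama$freq))
    g$frequency <- rama$freq[cbind(ti, ei)]
    g$outlier <- g$frequency < rama$cutoff
  } else {
    g$frequency <- numeric(0)
    g$outlier <- logical(0)
  }
  attr(g, "convention") <- "angles assigned to residue i of window (i-1, i, i+1, i+2)"
  g
}

#' Default van der Waals radii by element
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    MG = 1.73, ZN = 1.39, FE = 1.52, MN = 1.61, "NA" = 2.27, K = 2.75,
    CA = 2.31)
}

# backbone atom names excluded from consecutive-residue contact checks
.backbone_names <- c("N", "CA", "C", "O", "OXT",
                     "P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "C3'",
                     "O3'", "O4'", "C2'", "C1'", "O2'")

#' Close-contact (clash) detection
#'
#' Flags unordered atom pairs whose distance is below the sum of their van
#' der Waals radii minus `overlap_tolerance`. Pairs within one residue, and
#' backbone--backbone pairs between sequence-consecutive residues of the
#' same chain (which are covalently bonded or 1-3 neighbors), are excluded.
#' Uses a uniform spatial grid so only nearby pairs are examined; trace
#' models are handled like any other, with CA/P radii from the table.
#'
#' @param model an [atom_model].
#' @param vdw_table named numeric vector mapping element symbols to radii
#'   (A). Atoms whose element is absent are skipped with a warning.
#' @param overlap_tolerance allowed overlap in Angstrom before a pair is
#'   flagged (default 0.4).
#' @return A data frame with one row per clash: chain/resno/atom name for
#'   both partners, `distance` (A) and `overlap` (A, = r1 + r2 - d), plus
#'   atom row indices `i`, `j` into `model$atoms`.
#' @export
close_contacts <- function(model, vdw_table = default_vdw_radii(),
                           overlap_tolerance = 0.4) {
  stopifnot(inherits(model, "atom_model"))
  a <- model$atoms
  r <- unname(vdw_table[a$elesy])
  missing_el <- is.na(r)
  if (any(missing_el)) {
    warning("no van der Waals radius for element(s) ",
            paste(unique(a$elesy[missing_el]), collapse = ", "),
            "; skipping ", sum(missing_el), " atom(s)")
  }
  use <- which(!missing_el)
  empty <- data.frame(i = integer(), j = integer(),
                      chain_a = character(), resno_a = integer(),
                      atom_a = character(), chain_b = character(),
                      resno_b = integer(), atom_b = character(),
                      distance = numeric(), overlap = numeric(),
                      stringsAsFactors = FALSE)
  if (length(use) < 2L) return(empty)
  xyz <- as.matrix(a[use, c("x", "y", "z")])
  rr <- r[use]
  cutoff <- 2 * max(rr) - overlap_tolerance
  cs <- max(cutoff, 1e-6)
  ci <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cs)
  key <- ci[, 1] + 4096 * (ci[, 2] + 4096 * ci[, 3])
  cells <- split(seq_along(use), key)
  # half-space neighbor offsets so each cell pair is visited once
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
               (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
  pairs_i <- integer(0); pairs_j <- integer(0)
  keymap <- stats::setNames(seq_along(cells), names(cells))
  for (ck in seq_along(cells)) {
    members <- cells[[ck]]
    # within-cell pairs
    if (length(members) > 1L) {
      cmb <- utils::combn(members, 2L)
      pairs_i <- c(pairs_i, cmb[1L, ]); pairs_j <- c(pairs_j, cmb[2L, ])
    }
    # neighbor-cell pairs
    base <- ci[members[1L], ]
    for (o in seq_len(nrow(off))) {
      nk <- as.character((base[1] + off[o, 1]) +
                           4096 * ((base[2] + off[o, 2]) +
                                     4096 * (base[3] + off[o, 3])))
      nb <- keymap[nk]
      if (is.na(nb)) next
      other <- cells[[nb]]
      pairs_i <- c(pairs_i, rep(members, each = length(other)))
      pairs_j <- c(pairs_j, rep(other, times = length(members)))
    }
  }
  if (length(pairs_i) == 0L) return(empty)
  d <- sqrt(rowSums((xyz[pairs_i, , drop = FALSE] -
                       xyz[pairs_j, , drop = FALSE])^2))
  lim <- rr[pairs_i] + rr[pairs_j] - overlap_tolerance
  hit <- d < lim
  ii <- use[pairs_i[hit]]; jj <- use[pairs_j[hit]]; d <- d[hit]
  if (length(ii) == 0L) return(empty)
  # exclusions: same residue; bonded/1-3 backbone pairs of consecutive residues
  same_res <- a$chain[ii] == a$chain[jj] & a$resno[ii] == a$resno[jj] &
    (is.na(a$insert[ii]) == is.na(a$insert[jj])) &
    (ifelse(is.na(a$insert[ii]), "", a$insert[ii]) ==
       ifelse(is.na(a$insert[jj]), "", a$insert[jj]))
  consec_bb <- a$chain[ii] == a$chain[jj] &
    abs(a$resno[ii] - a$resno[jj]) == 1L &
    a$elety[ii] %in% .backbone_names & a$elety[jj] %in% .backbone_names
  keep <- !(same_res | consec_bb)
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  ord <- order(ii, jj)
  ii <- ii[ord]; jj <- jj[ord]; d <- d[ord]
  data.frame(i = ii, j = jj,
             chain_a = a$chain[ii], resno_a = a$resno[ii],
             atom_a = a$elety[ii], chain_b = a$chain[jj],
             resno_b = a$resno[jj], atom_b = a$elety[jj],
             distance = d,
             overlap = unname(vdw_table[a$elesy[ii]] +
                                vdw_table[a$elesy[jj]] - d),
             stringsAsFactors = FALSE)
}

#' Model atom inclusion at a contour level
#'
#' Samples the map density at every atom position (trilinear interpolation
#' by default, nearest-voxel as an option) and scores an atom as included
#' when the sampled density is at or above the contour level. Atoms outside
#' the map grid are counted as excluded and reported. The map origin is
#' honored: an atom at Cartesian position p samples grid coordinate
#' (p - origin) / voxel_size.
#'
#' @param model an [atom_model] with at least one atom.
#' @param map a [density_map] in the same coordinate frame.
#' @param contour density threshold (map units); typically the recommended
#'   display contour of the entry.
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return A list with `fraction` (included atoms / all atoms) and `atoms`,
#'   a data frame with per-atom `density`, `inside` and `included` flags.
#' @export
atom_inclusion <- function(model, map, contour,
                           method = c("trilinear", "nearest")) {
  stopifnot(inherits(model, "atom_model"), inherits(map, "density_map"))
  method <- match.arg(method)
  a <- model$atoms
  if (nrow(a) == 0L) stop("model has no atoms")
  d <- dim(map$data)
  g <- sweep(as.matrix(a[, c("x", "y", "z")]), 2, map$origin)
  g <- sweep(g, 2, map$voxel_size, "/")       # 0-based grid coordinates
  if (method == "nearest") {
    gi <- round(g)
    inside <- gi[, 1] >= 0 & gi[, 1] <= d[1] - 1 &
      gi[, 2] >= 0 & gi[, 2] <= d[2] - 1 &
      gi[, 3] >= 0 & gi[, 3] <= d[3] - 1
    dens <- rep(NA_real_, nrow(a))
    if (any(inside))
      dens[inside] <- map$data[gi[inside, , drop = FALSE] + 1]
  } else {
    inside <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
      g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
      g[, 3] >= 0 & g[, 3] <= d[3] - 1
    dens <- rep(NA_real_, nrow(a))
    if (any(inside)) {
      gg <- g[inside, , drop = FALSE]
      i0 <- pmin(floor(gg), matrix(rep(d - 2, each = nrow(gg)), ncol = 3))
      i0 <- pmax(i0, 0)
      f <- gg - i0
      acc <- 0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
          (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
          (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
        acc <- acc + w * map$data[cbind(i0[, 1] + dx, i0[, 2] + dy,
                                        i0[, 3] + dz) + 1]
      }
      dens[inside] <- acc
    }
  }
  included <- inside & !is.na(dens) & dens >= contour
  atoms <- data.frame(chain = a$chain, resno = a$resno, atom = a$elety,
                      density = dens, inside = inside, included = included,
                      stringsAsFactors = FALSE)
  list(fraction = sum(included) / nrow(a), atoms = atoms)
}

#' Run all trace-geometry and contact checks
#'
#' Convenience aggregator returning the individual findings tables plus
#' per-category outlier counts.
#'
#' @param model an [atom_model].
#' @param ref a [reference_distributions]; the pseudo-Ramachandran check is
#'   skipped (with `NULL` result) when `ref$rama` is absent.
#' @param vdw_table,overlap_tolerance passed to [close_contacts()].
#' @param sigma_multiplier passed to [caca_distance_outliers()].
#' @return An object of class `geometry_findings`: list with `caca`, `pp`,
#'   `rama`, `clashes` and `summary` (named counts, plus evaluated-pair
#'   totals).
#' @export
geometry_findings <- function(model, ref = default_reference_distributions(),
                              vdw_table = default_vdw_radii(),
                              overlap_tolerance = 0.4, sigma_multiplier = 3) {
  caca <- caca_distance_outliers(model, ref, sigma_multiplier)
  pp <- pp_distance_outliers(model, ref)
  rama <- if (!is.null(ref$rama)) pseudo_ramachandran(model, ref) else NULL
  clashes <- close_contacts(model, vdw_table, overlap_tolerance)
  structure(list(
    caca = caca, pp = pp, rama = rama, clashes = clashes,
    summary = list(
      caca_evaluated = nrow(caca), caca_outliers = sum(caca$outlier),
      pp_evaluated = nrow(pp), pp_outliers = sum(pp$outlier),
      rama_evaluated = if (is.null(rama)) NA_integer_ else nrow(rama),
      rama_outliers = if (is.null(rama)) NA_integer_ else sum(rama$outlier),
      clashes = nrow(clashes), n_atoms = nrow(model$atoms))),
    class = "geometry_findings")
}

#' @export
print.geometry_findings <- function(x, ...) {
  s <- x$summary
  cat("geometry_findings:\n")
  cat(sprintf("  CA-CA:  %d outliers / %d evaluated\n",
              s$caca_outliers, s$caca_evaluated))
  cat(sprintf("  P-P:    %d outliers / %d evaluated\n",
              s$pp_outliers, s$pp_evaluated))
  if (!is.na(s$rama_evaluated))
    cat(sprintf("  pseudo-Ramachandran: %d outliers / %d scored\n",
                s$rama_outliers, s$rama_evaluated))
  cat(sprintf("  close contacts: %d (of %d atoms)\n", s$clashes, s$n_atoms))
  invisible(x)
}
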