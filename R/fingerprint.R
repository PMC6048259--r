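#' Mass-weighted centre of mass of a residue
#'
#' @param system a `toy_system`
#' @param coords n x 3 coordinates
#' @param residue global residue id
#' @return 3-vector (Angstrom)
#' @export
residue_com <- function(system, coords, residue) {
  residue_com_coords(coords, residue_beads(system, residue), system$mass)
}

#' Residue-residue contact map over an ensemble
#'
#' A receptor residue and a ligand residue are in contact in a frame when
#' the distance between their centres of mass is within (inclusive) the
#' cutoff. Frequencies are fractions of frames.
#'
#' @param traj a `trajectory_ensemble`
#' @param system a `toy_system`
#' @param cutoff Angstrom (default 6)
#' @return object of class `contact_map`: frequency matrix (receptor
#'   residues x ligand residues), the cutoff and the frame count
#' @export
contact_map <- function(traj, system, cutoff = 6.0) {
  nf <- n_frames(traj)
  stopifnot(nf >= 1)
  rec <- which(system$residue_chain == "A")
  lig <- which(system$residue_chain == "B")
  freq <- matrix(0, length(rec), length(lig),
                 dimnames = list(paste0("A", system$residue_number[rec]),
                                 paste0("B", system$residue_number[lig])))
  rec_beads <- lapply(rec, residue_beads, system = system)
  lig_beads <- lapply(lig, residue_beads, system = system)
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    com_r <- t(vapply(rec_beads, residue_com_coords, numeric(3),
                      coords = x, mass = system$mass))
    com_l <- t(vapply(lig_beads, residue_com_coords, numeric(3),
                      coords = x, mass = system$mass))
    for (i in seq_along(rec)) {
      d <- sqrt(rowSums(sweep(com_l, 2, com_r[i, ])^2))
      freq[i, ] <- freq[i, ] + (d <= cutoff)
    }
  }
  structure(list(freq = freq / nf, cutoff = cutoff, n_frames = nf),
            class = "contact_map")
}

#' Signed contact-map difference (mutant minus wild type)
#'
#' Negative entries mark interactions weakened by the mutation.
#'
#' @param map_mut,map_wt `contact_map` objects on matching residue grids
#' @return signed frequency-difference matrix
#' @export
contact_difference <- function(map_mut, map_wt) {
  stopifnot(identical(dim(map_mut$freq), dim(map_wt$freq)))
  map_mut$freq - map_wt$freq
}

#' Detect hydrogen bonds in a configuration
#'
#' A bond is recorded between the two chains whenever an acceptor of one
#' chain is within (inclusive) 3.0 Angstrom of a donor heavy atom of the
#' other chain and the acceptor-hydrogen-donor angle is at least 135
#' degrees. Distances are donor-heavy-atom to acceptor-heavy-atom. Several
#' bonds may be recorded for one residue pair in one frame.
#'
#' @param system a `toy_system` with donor sites (donor bead, hydrogen
#'   bead) and acceptor beads defined
#' @param coords n x 3 coordinates
#' @param dist_cutoff Angstrom
#' @param angle_min degrees
#' @return data frame: donor, hydrogen, acceptor bead indices, distance,
#'   angle, donor and acceptor global residue ids
#' @export
detect_hbonds <- function(system, coords, dist_cutoff = 3.0, angle_min = 135) {
  out <- list()
  donors <- system$donors
  if (nrow(donors) > 0 && any(is.na(donors[, 2])))
    stop("configuration error: donor without an explicit hydrogen bead")
  chain_of_bead <- system$residue_chain[system$residue_id]
  for (d in seq_len(nrow(donors))) {
    D <- donors[d, 1]; H <- donors[d, 2]
    for (A in system$acceptors) {
      if (chain_of_bead[A] == chain_of_bead[D]) next
      dist <- sqrt(sum((coords[D, ] - coords[A, ])^2))
      if (dist > dist_cutoff) next
      v1 <- coords[A, ] - coords[H, ]
      v2 <- coords[D, ] - coords[H, ]
      cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(max(-1, min(1, cth))) * 180 / pi
      if (ang >= angle_min) {
        out[[length(out) + 1L]] <- data.frame(
          donor = D, hydrogen = H, acceptor = A,
          distance = dist, angle = ang,
          donor_res = system$residue_id[D],
          acceptor_res = system$residue_id[A])
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
               distance = numeric(), angle = numeric(),
               donor_res = integer(), acceptor_res = integer())
}

#' Subsample frame indices at a fixed stride
#'
#' Keeps every `stride`-th element starting from the first, so the result
#' has `ceiling(n / stride)` elements.
#'
#' @param frame_indices vector of frame indices (or any vector)
#' @param stride positive integer
#' @export
subsample <- function(frame_indices, stride) {
  stopifnot(stride >= 1, stride == round(stride))
  frame_indices[seq(1, length(frame_indices), by = stride)]
}

#' Total hydrogen-bond counts per residue pair over an ensemble
#'
#' Frames are subsampled at `stride` (starting from the first) and bonds
#' are counted with multiplicity.
#'
#' @param traj a `trajectory_ensemble`
#' @param system a `toy_system`
#' @param stride frame subsampling stride
#' @inheritParams detect_hbonds
#' @return data frame: `pair` label (`"A<i>-B<j>"`, donor-side residue
#'   first), `count`
#' @export
hbond_pair_counts <- function(traj, system, stride = 1L, dist_cutoff = 3.0,
                              angle_min = 135) {
  frames <- subsample(seq_len(n_frames(traj)), stride)
  tally <- new.env()
  for (f in frames) {
    hb <- detect_hbonds(system, frame_coords(traj, f), dist_cutoff, angle_min)
    if (!nrow(hb)) next
    lab <- paste0(
      system$residue_chain[hb$donor_res], system$residue_number[hb$donor_res],
      "-",
      system$residue_chain[hb$acceptor_res], system$residue_number[hb$acceptor_res])
    for (L in lab) assign(L, (if (exists(L, tally)) get(L, tally) else 0) + 1,
                          tally)
  }
  keys <- ls(tally)
  data.frame(pair = keys,
             count = vapply(keys, get, numeric(1), envir = tally),
             row.names = NULL)
}

#' Per-frame total cross-chain hydrogen-bond counts
#' @inheritParams hbond_pair_counts
#' @return integer vector, one total per (subsampled) frame
#' @export
hbond_counts_frames <- function(traj, system, stride = 1L, dist_cutoff = 3.0,
                                angle_min = 135) {
  frames <- subsample(seq_len(n_frames(traj)), stride)
  vapply(frames, function(f)
    nrow(detect_hbonds(system, frame_coords(traj, f), dist_cutoff, angle_min)),
    integer(1))
}

#' Round half toward zero
#'
#' Display rounding used for hydrogen-bond ratio tables: ties at the final
#' digit round toward zero (e.g. 0.375 to two decimals is 0.37), everything
#' else rounds to nearest.
#'
#' @param x non-negative numeric
#' @param digits decimal places
#' @export
round_half_down <- function(x, digits = 2) {
  s <- 10^digits
  ceiling(x * s - 0.5) / s
}

#' Mutant/wild-type hydrogen-bond ratio table
#'
#' For each residue pair, `HbR1 = count_mut_clamped / count_wt_clamped`
#' (the nanobody-present condition) and
#' `HbR2 = count_mut_free / count_wt_free` (nanobody-absent), with the
#' convention that a zero denominator gives a ratio of 0. The comparison
#' flag is `"Yes"` when `HbR1 > HbR2` (the clamped condition inflates the
#' mutant's hydrogen bonding), `"No"` when `HbR1 <= HbR2`, and `"-"`
#' (indeterminate) when the mutant count is zero in both conditions.
#' Stored ratios are unrounded; use [round_half_down()] for display.
#'
#' @param pairs residue-pair labels
#' @param count_wt_clamped,count_mut_clamped,count_wt_free,count_mut_free
#'   hydrogen-bond counts per pair in the four systems
#' @return data frame of class `hbr_table`
#' @export
hbr_table <- function(pairs, count_wt_clamped, count_mut_clamped,
                      count_wt_free, count_mut_free) {
  stopifnot(length(pairs) == length(count_wt_clamped),
            length(pairs) == length(count_mut_clamped),
            length(pairs) == length(count_wt_free),
            length(pairs) == length(count_mut_free))
  counts <- cbind(count_wt_clamped, count_mut_clamped,
                  count_wt_free, count_mut_free)
  if (any(counts < 0)) stop("hydrogen-bond counts must be >= 0")
  ratio0 <- function(num, den) ifelse(den == 0, 0, num / den)
  hbr1 <- ratio0(count_mut_clamped, count_wt_clamped)
  hbr2 <- ratio0(count_mut_free, count_wt_free)
  flag <- ifelse(count_mut_clamped == 0 & count_mut_free == 0, "-",
                 ifelse(hbr1 > hbr2, "Yes", "No"))
  structure(data.frame(pair = pairs,
                       wt_clamped = count_wt_clamped,
                       mut_clamped = count_mut_clamped, hbr1 = hbr1,
                       wt_free = count_wt_free, mut_free = count_mut_free,
                       hbr2 = hbr2, flag = flag, row.names = NULL),
            class = c("hbr_table", "data.frame"))
}

#' Published interface hydrogen-bond counts for the four TorsinA-LULL1 systems
#'
#' Per-residue-pair hydrogen-bond counts reported from all-atom simulations
#' of the wild-type and DeltaE303 TorsinA-LULL1 complexes, each with and
#' without the VHH-BS2 crystallization nanobody, together with the
#' hydrogen-bond ratios and comparison flags as printed (shipped as plain
#' text in `extdata`). These serve as reference inputs for the ratio-table
#' statistic; the counts themselves are not recomputed here.
#'
#' @return data frame with columns `pair`, `tlv`, `tdelv`, `hbr1_printed`,
#'   `tl`, `tdel`, `hbr2_printed`, `flag_printed`
#' @export
published_hbond_counts <- function() {
  path <- system.file("extdata", "interface_hbond_counts.tsv",
                      package = "deltabind", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "integer",
                                   "character", "character"))
}

#' Significance of a hydrogen-bond count difference between two ensembles
#'
#' Per-frame totals are averaged over non-overlapping blocks (to blunt
#' frame autocorrelation) and compared by a two-sided Mann-Whitney U test.
#'
#' @param per_frame_counts_a,per_frame_counts_b per-frame total counts
#' @param block block length in frames
#' @return two-sided p-value
#' @export
hbond_count_significance <- function(per_frame_counts_a, per_frame_counts_b,
                                     block = 10L) {
  bm <- function(x) {
    g <- (seq_along(x) - 1L) %/% block
    as.numeric(tapply(x, g, mean))
  }
  a <- bm(per_frame_counts_a); b <- bm(per_frame_counts_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two blocks per ensemble")
  suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
}

# Kabsch rotation taking centred P onto centred Q
kabsch_rotation <- function(P, Q) {
  C <- crossprod(P, Q)
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares superposition RMSD
#'
#' Optimal-rotation (Kabsch) superposition of `coords` onto `ref_coords`
#' over the selection, then the root-mean-square deviation over that
#' selection.
#'
#' @param coords,ref_coords n x 3 coordinate matrices
#' @param selection bead indices to fit and measure on
#' @return RMSD in Angstrom
#' @export
rmsd <- function(coords, ref_coords, selection = seq_len(nrow(coords))) {
  P <- coords[selection, , drop = FALSE]
  Q <- ref_coords[selection, , drop = FALSE]
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  R <- kabsch_rotation(P, Q)
  sqrt(mean(rowSums((P %*% R - Q)^2)))
}

# superpose frame coords onto ref over selection; returns transformed coords
superpose_frame <- function(coords, ref_coords, selection) {
  cp <- colMeans(coords[selection, , drop = FALSE])
  cq <- colMeans(ref_coords[selection, , drop = FALSE])
  P <- sweep(coords[selection, , drop = FALSE], 2, cp)
  Q <- sweep(ref_coords[selection, , drop = FALSE], 2, cq)
  R <- kabsch_rotation(P, Q)
  sweep(sweep(coords, 2, cp) %*% R, 2, cq, `+`)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the first frame, a mean structure is formed,
#' frames are re-superposed onto that mean, and each residue's
#' centre-of-mass fluctuation about its mean position is reported.
#'
#' @param traj a `trajectory_ensemble`
#' @param system a `toy_system`
#' @param selection beads used for the superposition fit
#' @return named vector of per-residue RMSF (Angstrom)
#' @export
rmsf <- function(traj, system, selection = seq_len(nrow(system$pos))) {
  nf <- n_frames(traj)
  aligned <- lapply(seq_len(nf), function(f)
    superpose_frame(frame_coords(traj, f), frame_coords(traj, 1), selection))
  mref <- Reduce(`+`, aligned) / nf
  aligned <- lapply(aligned, superpose_frame, ref_coords = mref,
                    selection = selection)
  nres <- length(system$residue_chain)
  coms <- array(NA_real_, c(nf, nres, 3))
  for (f in seq_len(nf)) for (r in seq_len(nres))
    coms[f, r, ] <- residue_com_coords(aligned[[f]], residue_beads(system, r),
                                       system$mass)
  mcom <- apply(coms, c(2, 3), mean)
  out <- sqrt(vapply(seq_len(nres), function(r)
    mean(rowSums(sweep(coms[, r, , drop = TRUE], 2, mcom[r, ])^2)),
    numeric(1)))
  names(out) <- paste0(system$residue_chain, system$residue_number)
  out
}

#' Native residue-residue contacts of a reference structure
#'
#' @param system a `toy_system`
#' @param ref_coords reference coordinates (default: the system's)
#' @param cutoff contact cutoff (Angstrom)
#' @return data frame of cross-chain residue pairs (global ids) in contact
#' @export
native_contacts <- function(system, ref_coords = system$pos, cutoff = 6.0) {
  rec <- which(system$residue_chain == "A")
  lig <- which(system$residue_chain == "B")
  out <- list()
  for (i in rec) for (j in lig) {
    d <- sqrt(sum((residue_com(system, ref_coords, i) -
                     residue_com(system, ref_coords, j))^2))
    if (d <= cutoff) out[[length(out) + 1L]] <- data.frame(res_i = i, res_j = j)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(res_i = integer(), res_j = integer())
}

#' Fraction of native contacts present in a configuration
#'
#' @param coords n x 3 coordinates
#' @param system a `toy_system`
#' @param reference_contacts data frame from [native_contacts()]
#' @param cutoff contact cutoff (Angstrom)
#' @return Q in `[0, 1]`
#' @export
native_contact_fraction <- function(coords, system, reference_contacts,
                                    cutoff = 6.0) {
  if (!nrow(reference_contacts)) stop("empty reference contact set")
  present <- vapply(seq_len(nrow(reference_contacts)), function(k) {
    d <- sqrt(sum((residue_com(system, coords, reference_contacts$res_i[k]) -
                     residue_com(system, coords, reference_contacts$res_j[k]))^2))
    d <= cutoff
  }, logical(1))
  mean(present)
}
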