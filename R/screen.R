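#' Read a protein structure for dye modelling
#'
#' Thin wrapper over the bio3d PDB reader keeping the first model and altloc
#' A heavy atoms (hydrogens are irrelevant for dye clash tests).
#'
#' @param path PDB file path.
#' @return tibble of atoms: `eleno`, `elety`, `resid`, `resno`, `chain`,
#'   `x`, `y`, `z`, `elesy`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM" | a$type == "HETATM", ]
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), ]
  el <- a$elesy
  if (is.null(el) || all(is.na(el))) el <- substr(trimws(a$elety), 1, 1)
  a <- a[toupper(substr(trimws(el), 1, 1)) != "H", ]
  el <- el[toupper(substr(trimws(el), 1, 1)) != "H"]
  tibble::tibble(eleno = a$eleno, elety = trimws(a$elety),
                 resid = a$resid, resno = a$resno, chain = a$chain,
                 x = a$x, y = a$y, z = a$z, elesy = trimws(el))
}

# locate an attachment atom (CB by default, CA fallback) for a residue
attachment_atom <- function(atoms, resno, atom_name = NULL, chain = NULL) {
  sel <- atoms$resno == resno
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  cand <- atoms[sel, ]
  if (nrow(cand) == 0) return(NULL)
  nm <- atom_name %||% if ("CB" %in% cand$elety) "CB" else "CA"
  at <- cand[cand$elety == nm, ]
  if (nrow(at) == 0) return(NULL)
  at[1, ]
}

# ACV clouds for one labelling position on one structure; the attachment
# atom itself is removed from the obstacle list
position_cloud <- function(atoms, resno, spec, chain = NULL,
                           spacing_A = 0.9) {
  at <- attachment_atom(atoms, resno, chain = chain)
  if (is.null(at)) return(NULL)
  obstacles <- atoms[atoms$eleno != at$eleno, ]
  compute_acv(obstacles, c(at$x, at$y, at$z), spec, spacing_A)
}

#' Screen structural models against experimental FRET distance sets
#'
#' For every structure and every conformational state's distance set, donor
#' and acceptor ACV clouds are computed at the labelled residues, the model
#' mean inter-dye distance is compared with the experimental one, and the
#' error function
#' \deqn{\chi^2_{r,FPS} = \frac{1}{N} \sum_i
#'   \frac{(\langle R_{DA}\rangle^{(i)}_{exp} -
#'          \langle R_{DA}\rangle^{(i)}_{model})^2}
#'        {(\Delta R^{(i)}_{DA,tot})^2}}
#' is accumulated, using the asymmetric uncertainty side that matches the
#' sign of the residual. Structures are ranked per state; a linear
#' regression of experimental on model distances is reported per
#' (structure, state).
#'
#' @param structures named list of atom tibbles (see [read_structure()]).
#' @param distance_set tibble with columns `pair_id`, `don_res`, `acc_res`,
#'   `state`, `R_exp_A`, `dR_minus_A`, `dR_plus_A`.
#' @param donor_spec,acceptor_spec [dye_spec()]s.
#' @param spacing_A ACV grid spacing.
#' @return `screen_result`: list with `chi2` tibble (per structure x state),
#'   `details` (per pair), `ranking`.
#' @export
screen_structures <- function(structures, distance_set,
                              donor_spec = dye_spec_alexa488(),
                              acceptor_spec = dye_spec_alexa647(),
                              spacing_A = 0.9) {
  distance_set <- tibble::as_tibble(distance_set)
  need <- c("pair_id", "don_res", "acc_res", "state", "R_exp_A",
            "dR_minus_A", "dR_plus_A")
  stopifnot(all(need %in% names(distance_set)))
  if (any(distance_set$R_exp_A <= 0)) stop("distances must be > 0")
  if (any(distance_set$dR_minus_A <= 0) || any(distance_set$dR_plus_A <= 0)) {
    stop("uncertainties must be > 0")
  }
  if (is.null(names(structures))) {
    names(structures) <- paste0("structure", seq_along(structures))
  }
  details <- purrr::imap_dfr(structures, function(atoms, sname) {
    # cache clouds per labelling position (donor and acceptor separately)
    pos_d <- unique(distance_set$don_res)
    pos_a <- unique(distance_set$acc_res)
    clouds_d <- stats::setNames(lapply(pos_d, function(p)
      tryCatch(position_cloud(atoms, p, donor_spec, spacing_A = spacing_A),
               error = function(e) NULL)), as.character(pos_d))
    clouds_a <- stats::setNames(lapply(pos_a, function(p)
      tryCatch(position_cloud(atoms, p, acceptor_spec, spacing_A = spacing_A),
               error = function(e) NULL)), as.character(pos_a))
    purrr::pmap_dfr(distance_set, function(pair_id, don_res, acc_res, state,
                                           R_exp_A, dR_minus_A, dR_plus_A, ...) {
      cd <- clouds_d[[as.character(don_res)]]
      ca <- clouds_a[[as.character(acc_res)]]
      if (is.null(cd) || is.null(ca)) {
        warning("structure ", sname, ": pair ", pair_id,
                " skipped (missing residue or buried site)")
        return(tibble::tibble(structure = sname, pair_id = pair_id,
                              don_res = don_res, acc_res = acc_res,
                              state = state, R_exp_A = R_exp_A,
                              R_model_A = NA_real_, resid_A = NA_real_,
                              dR_used_A = NA_real_))
      }
      m <- interdye_metrics(cd, ca)
      resid <- R_exp_A - m$R_da_mean
      dR <- if (resid >= 0) dR_plus_A else dR_minus_A
      tibble::tibble(structure = sname, pair_id = pair_id,
                     don_res = don_res, acc_res = acc_res, state = state,
                     R_exp_A = R_exp_A, R_model_A = m$R_da_mean,
                     resid_A = resid, dR_used_A = dR)
    })
  })
  chi2 <- details |>
    dplyr::filter(is.finite(.data$R_model_A)) |>
    dplyr::group_by(.data$structure, .data$state) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      chi2r_fps = mean((.data$resid_A / .data$dR_used_A)^2),
      slope = if (dplyr::n() >= 2)
        stats::coef(stats::lm(R_exp_A ~ R_model_A))[2] else NA_real_,
      intercept = if (dplyr::n() >= 2)
        stats::coef(stats::lm(R_exp_A ~ R_model_A))[1] else NA_real_,
      .groups = "drop") |>
    dplyr::group_by(.data$state) |>
    dplyr::mutate(rank = rank(.data$chi2r_fps)) |>
    dplyr::ungroup()
  ranking <- chi2 |>
    dplyr::filter(.data$rank == 1) |>
    dplyr::select(dplyr::all_of(c("state", "structure", "chi2r_fps")))
  structure(list(chi2 = chi2, details = details, ranking = ranking),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  print(x$chi2)
  cat("best per state:\n")
  print(x$ranking)
  invisible(x)
}

#' @export
tidy.screen_result <- function(x, ...) x$chi2

# ---- structure superposition and clustering --------------------------------

# Kabsch optimal superposition: returns RMSD of Y onto X (n x 3 matrices)
kabsch_rmsd <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y))
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  S <- svd(crossprod(Yc, Xc))
  d <- sign(det(S$u %*% t(S$v)))
  U <- S$u %*% diag(c(1, 1, d)) %*% t(S$v)
  Yr <- Yc %*% U
  sqrt(mean(rowSums((Yr - Xc)^2)))
}

#' Cluster structures by C-alpha RMSD
#'
#' Pairwise C-alpha RMSD after optimal (Kabsch) superposition, agglomerative
#' complete-linkage clustering, dendrogram cut at `cutoff_A`. Complete
#' linkage guarantees every intra-cluster pair stays within the cutoff. The
#' representative of each cluster is its medoid (smallest summed RMSD to the
#' other members).
#'
#' @param structures named list of atom tibbles sharing a common C-alpha
#'   mapping (same residues in the same order after selection).
#' @param cutoff_A dendrogram height cut (Angstrom), default 1.8.
#' @return tibble with `structure`, `cluster`, `representative` plus
#'   attribute `"rmsd"` (the distance matrix).
#' @export
cluster_structures <- function(structures, cutoff_A = 1.8) {
  stopifnot(length(structures) >= 1)
  if (is.null(names(structures))) {
    names(structures) <- paste0("structure", seq_along(structures))
  }
  ca <- lapply(structures, function(a) {
    m <- as.matrix(a[a$elety == "CA", c("x", "y", "z")])
    if (nrow(m) == 0) stop("structure without C-alpha atoms")
    m
  })
  ns <- vapply(ca, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop("structures are not alignable: differing C-alpha counts")
  }
  k <- length(ca)
  D <- matrix(0, k, k, dimnames = list(names(ca), names(ca)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) D[i, j] <- D[j, i] <- kabsch_rmsd(ca[[i]], ca[[j]])
  }
  cl <- if (k == 1) 1L else {
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    stats::cutree(hc, h = cutoff_A)
  }
  reps <- vapply(unique(cl), function(g) {
    members <- which(cl == g)
    if (length(members) == 1) return(names(ca)[members])
    sums <- rowSums(D[members, members, drop = FALSE])
    names(ca)[members[which.min(sums)]]
  }, character(1))
  out <- tibble::tibble(structure = names(ca), cluster = unname(cl),
                        representative = reps[match(cl, unique(cl))])
  attr(out, "rmsd") <- D
  out
}
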