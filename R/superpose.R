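#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `R %*% mobile[i, ] + t` and `target[i, ]` over positional
#' correspondences. Reflections are excluded by correcting the sign of the
#' smallest singular value, so the returned rotation always has determinant
#' +1.
#'
#' @param mobile numeric N x 3 matrix of coordinates to move.
#' @param target numeric N x 3 matrix of reference coordinates.
#' @return an object of class `rigid_transform`: list with `rotation`
#'   (3 x 3, proper orthonormal), `translation` (length-3, Angstrom) and
#'   `fit_rmsd` (Angstrom, post-fit).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (ncol(mobile) != 3L || ncol(target) != 3L)
    stop("coordinate matrices must have 3 columns")
  n <- nrow(mobile)
  if (n != nrow(target)) stop("mobile and target must have the same number of points")
  if (n < 3L) stop("superposition needs at least 3 points")
  if (!all(is.finite(mobile)) || !all(is.finite(target)))
    stop("non-finite coordinates")

  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  C <- crossprod(A, B)                    # 3x3 covariance
  s <- svd(C)
  # collinear/degenerate point sets leave the rotation underdetermined
  scale <- sqrt(sum(A^2) * sum(B^2)) / n
  if (scale < 1e-12 || s$d[2] < 1e-9 * max(s$d[1], scale))
    stop("degenerate (collinear or coincident) point set: rotation underdetermined")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum((fitted - B)^2) / n)
  tr <- as.numeric(ct - R %*% cm)
  structure(list(rotation = R, translation = tr, fit_rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform: fit RMSD", format(x$fit_rmsd, digits = 6), "A\n")
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform`.
#' @param coords numeric N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

# project an arbitrary 3x3 matrix onto the nearest proper rotation
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Extend a protofibril by replicating filaments along the growth axis
#'
#' Amyloid protofibrils are stacks of near-identical chains (filaments)
#' related by a screw operator (a rise of ~4.7-4.8 Angstrom plus a small
#' twist). The operator is estimated by Kabsch superposition of the backbone
#' atoms (N, CA, C) of each consecutive chain pair, averaged over all pairs
#' (the averaged rotation is re-projected onto the rotation group), and then
#' applied repeatedly to the terminal chain until `target_copies` chains
#' exist. Original atoms are never moved; new chains receive fresh chain
#' identifiers and continuing serial numbers.
#'
#' @param model a `protofibril` with >= 2 protein chains of identical
#'   sequence and per-residue atom counts.
#' @param target_copies desired total number of protein chains.
#' @return the extended `protofibril`.
#' @export
extend_protofibril <- function(model, target_copies) {
  prot <- model_atoms(model, "protein")
  chains <- unique(prot$chain_id)
  k <- length(chains)
  if (k < 2L) stop("need at least 2 protein chains to estimate the stacking operator")
  if (target_copies < k) stop("target_copies (", target_copies,
                              ") is less than the current chain count (", k, ")")
  if (target_copies == k) return(model)

  per_chain <- lapply(chains, function(cid) prot[prot$chain_id == cid, , drop = FALSE])
  sig <- vapply(per_chain, function(a) {
    rt_key <- paste(a$res_seq[!duplicated(paste(a$res_seq, a$ins_code))], collapse = ",")
    paste(rt_key, paste(a$res_name, a$name, collapse = "|"), sep = ";")
  }, character(1))
  if (length(unique(sig)) != 1L)
    stop("chains have mismatched residue sequences or atom counts; cannot replicate")

  bb <- lapply(per_chain, function(a)
    atom_coords(a[a$name %in% c("N", "CA", "C"), , drop = FALSE]))
  tfs <- lapply(seq_len(k - 1L), function(i) kabsch_superpose(bb[[i]], bb[[i + 1L]]))
  Rbar <- nearest_rotation(Reduce(`+`, lapply(tfs, `[[`, "rotation")) / (k - 1L))
  tbar <- colMeans(do.call(rbind, lapply(tfs, `[[`, "translation")))
  op <- structure(list(rotation = Rbar, translation = tbar, fit_rmsd = NA_real_),
                  class = "rigid_transform")

  used <- unique(model$atoms$chain_id)
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
  n_new <- target_copies - k
  if (n_new > length(pool)) stop("not enough free chain identifiers for ", n_new, " new chains")

  atoms <- model$atoms
  last <- per_chain[[k]]
  serial0 <- max(atoms$serial)
  for (j in seq_len(n_new)) {
    xyz <- apply_transform(op, atom_coords(last))
    new_chain <- last
    new_chain$x <- xyz[, 1]; new_chain$y <- xyz[, 2]; new_chain$z <- xyz[, 3]
    new_chain$chain_id <- pool[j]
    new_chain$serial <- serial0 + seq_len(nrow(new_chain))
    serial0 <- serial0 + nrow(new_chain)
    atoms <- rbind(atoms, new_chain)
    last <- new_chain
  }
  rownames(atoms) <- NULL
  protofibril(atoms, ligand_resnames = model$ligand_resnames, source = model$source)
}
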