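# Ensemble distance screen: sugar protons (H3', H4') near imino protons
# across a multi-model NMR structure, used as a control for magnetization
# transfer artifacts from protons resonating near water.

# normalize sugar-proton naming dialects: H4' / H4* / H4(prime) -> H4'
normalize_atom_name <- function(x) {
  x <- gsub("′", "'", x, fixed = TRUE)
  x <- gsub("*", "'", x, fixed = TRUE)
  x
}

#' Load a multi-model structure
#'
#' Reads a (possibly multi-model) PDB file via [bio3d::read.pdb], retaining
#' hydrogens, and returns one coordinate set per MODEL record. Atom names
#' are normalized (`H4*`, `H4` + prime mark and `H4'` all become `H4'`).
#' Files without hydrogen atoms are rejected — the contact screen needs
#' protons.
#'
#' @param path path to a PDB file.
#' @return An object of class `"structure_models"`: list with `atoms` (data
#'   frame: `resid`, `resno`, `elety`) and `xyz` (matrix, one row per model,
#'   3 columns per atom).
#' @export
load_models <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, hex = TRUE,
                         verbose = FALSE)
  atoms <- pdb$atom
  atoms$elety <- normalize_atom_name(atoms$elety)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atoms) || anyNA(xyz))
    stop("models have mismatched atom rosters", call. = FALSE)
  if (!any(grepl("^H", atoms$elety)))
    stop("structure contains no hydrogen atoms; the contact screen needs protons",
         call. = FALSE)
  structure(list(atoms = atoms[, c("resid", "resno", "elety")],
                 xyz = xyz, n_models = nrow(xyz)),
            class = "structure_models")
}

#' @export
print.structure_models <- function(x, ...) {
  cat(sprintf("Structure ensemble: %d models, %d atoms (%d hydrogens)\n",
              x$n_models, nrow(x$atoms), sum(grepl("^H", x$atoms$elety))))
  invisible(x)
}

# default imino-proton donors: guanine H1, thymine/uracil H3 (DNA and RNA
# residue-name dialects)
default_imino_donors <- function() {
  list(G = "H1", DG = "H1", GUA = "H1",
       T = "H3", DT = "H3", THY = "H3",
       U = "H3", RU = "H3", URA = "H3")
}

#' Screen an ensemble for sugar protons near imino protons
#'
#' For every (imino proton, sugar proton) pair, counts the models of the
#' ensemble in which the Euclidean distance is below `cutoff`; a pair is
#' reported when the count reaches `min_models`. Defaults implement the
#' conservative reading of "in more than six of twelve structures": at
#' least 7 models, strict `<` comparison at 5 Angstrom.
#'
#' @param models a [load_models] result.
#' @param donor_atoms named list mapping residue names to their imino-proton
#'   atom name (default: G/DG H1, T/DT/U H3).
#' @param target_atoms sugar-proton atom names to screen (normalized names).
#' @param cutoff distance cutoff, Angstrom.
#' @param min_models minimum number of models in which the distance must
#'   satisfy the cutoff.
#' @param strict if `TRUE` (default) the comparison is `distance < cutoff`;
#'   `FALSE` uses `<=` for sensitivity checks.
#' @return Data frame: `donor_resid`, `donor_resno`, `target_resid`,
#'   `target_resno`, `target_atom`, `n_models_satisfying`, `min_dist`,
#'   `max_dist` — one row per reported pair, sorted by donor residue number.
#' @export
imino_sugar_contacts <- function(models,
                                 donor_atoms = default_imino_donors(),
                                 target_atoms = c("H3'", "H4'"),
                                 cutoff = 5.0, min_models = 7,
                                 strict = TRUE) {
  stopifnot(inherits(models, "structure_models"))
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (min_models > models$n_models)
    stop("min_models exceeds the number of models", call. = FALSE)
  at <- models$atoms
  donor_idx <- which(mapply(function(res, ele) {
    !is.null(donor_atoms[[res]]) && ele %in% donor_atoms[[res]]
  }, at$resid, at$elety))
  target_idx <- which(at$elety %in% target_atoms)
  if (length(donor_idx) == 0 || length(target_idx) == 0)
    stop("empty donor or target atom selection", call. = FALSE)

  rows <- list()
  for (d in donor_idx) {
    dxyz <- models$xyz[, (3 * d - 2):(3 * d), drop = FALSE]
    for (a in target_idx) {
      axyz <- models$xyz[, (3 * a - 2):(3 * a), drop = FALSE]
      dist <- sqrt(rowSums((dxyz - axyz)^2))
      hit <- if (strict) dist < cutoff else dist <= cutoff
      n_hit <- sum(hit)
      if (n_hit >= min_models) {
        rows[[length(rows) + 1]] <- data.frame(
          donor_resid = at$resid[d], donor_resno = at$resno[d],
          target_resid = at$resid[a], target_resno = at$resno[a],
          target_atom = at$elety[a],
          n_models_satisfying = n_hit,
          min_dist = min(dist), max_dist = max(dist))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_resid = character(), donor_resno = integer(),
               target_resid = character(), target_resno = integer(),
               target_atom = character(), n_models_satisfying = integer(),
               min_dist = numeric(), max_dist = numeric())
  out <- out[order(out$donor_resno, out$target_resno, out$target_atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a contact report as TSV
#'
#' @param contacts result of [imino_sugar_contacts].
#' @param path output file.
#' @export
write_contact_report <- function(contacts, path) {
  write_tsv(contacts, path)
  invisible(path)
}
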