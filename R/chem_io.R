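# Molecule parsing, 3D conformer generation and tabular I/O.
#
# All chemistry (SMILES interpretation, aromaticity perception, 3D
# embedding, MMFF94 minimisation) is delegated to Open Babel through
# ChemmineOB. Structures are exchanged in MOL2 because it preserves the
# aromatic bond type that the 4-category bond featurisation needs.

.BOND_ORDERS <- c("single", "double", "triple", "aromatic")

.ob_convert <- function(source, from = "SMI", to = "MOL2", opts = NULL) {
  if (is.null(opts)) {
    ChemmineOB::convertFormat(from, to, source = source)
  } else {
    ChemmineOB::convertFormat(from, to, source = source,
                              options = data.frame(names = opts,
                                                   args = rep("", length(opts)),
                                                   stringsAsFactors = FALSE))
  }
}

# 3D embedding backend: distance-geometry embedding with experimental
# torsion knowledge (ETKDG) plus MMFF94 minimisation, via RDKit in a
# batched python subprocess. Seeded and bit-deterministic. Returns a named
# list (by tag) of list(status, minimized, elements, coords).
.rdkit_embed <- function(smiles, tags, seed = 1L) {
  script <- system.file("python", "embed_conformers.py",
                        package = "graphccs", mustWork = TRUE)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste(smiles, tags), fin)
  status <- suppressWarnings(
    system2("python", c(script, fin, fout, as.character(as.integer(seed))),
            stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(fout)) {
    stop(errorCondition("conformer backend (python/rdkit) failed to run",
                        class = c("graphccs_embedding_failed",
                                  "graphccs_error")))
  }
  lines <- readLines(fout, warn = FALSE)
  starts <- grep("^#BEGIN ", lines)
  ends <- grep("^#END", lines)
  out <- lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    st <- strsplit(blk[2], " ")[[1]]
    res <- list(status = st[2], minimized = as.integer(st[3]),
                elements = character(0),
                coords = matrix(0, 0, 3))
    if (st[2] == "ok" && length(blk) > 3) {
      af <- strsplit(blk[3:(length(blk) - 1)], " ")
      res$elements <- vapply(af, `[[`, "", 1)
      res$coords <- t(vapply(af, function(f) as.numeric(f[2:4]), numeric(3)))
    }
    res
  })
  names(out) <- sub("^#BEGIN ", "", lines[starts])
  out
}

# Parse MOL2 text (possibly several molecules) into a list of
# list(name, elements, coords, bonds) where bonds has columns i, j, order.
.parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    name <- trimws(blk[2])
    a0 <- grep("^@<TRIPOS>ATOM", blk)[1]
    b0 <- grep("^@<TRIPOS>BOND", blk)[1]
    sect_end <- function(from) {
      nxt <- grep("^@<TRIPOS>", blk)
      nxt <- nxt[nxt > from]
      if (length(nxt)) min(nxt) - 1L else length(blk)
    }
    atom_lines <- blk[(a0 + 1L):sect_end(a0)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    af <- strsplit(trimws(atom_lines), "\\s+")
    elements <- vapply(af, function(f) sub("\\..*$", "", f[6]), character(1))
    coords <- t(vapply(af, function(f) as.numeric(f[3:5]), numeric(3)))
    bonds <- data.frame(i = integer(0), j = integer(0),
                        order = character(0), stringsAsFactors = FALSE)
    if (!is.na(b0)) {
      bond_lines <- blk[(b0 + 1L):sect_end(b0)]
      bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
      if (length(bond_lines)) {
        bf <- strsplit(trimws(bond_lines), "\\s+")
        bonds <- data.frame(
          i = vapply(bf, function(f) as.integer(f[2]), integer(1)),
          j = vapply(bf, function(f) as.integer(f[3]), integer(1)),
          order = vapply(bf, function(f) f[4], character(1)),
          stringsAsFactors = FALSE
        )
        # MOL2 types: 1/2/3 = single/double/triple, ar = aromatic,
        # am (amide) treated as single.
        map <- c(`1` = "single", `2` = "double", `3` = "triple",
                 ar = "aromatic", am = "single")
        bonds$order <- unname(map[bonds$order])
      }
    }
    list(name = name, elements = elements, coords = coords, bonds = bonds)
  })
}

.ring_atoms <- function(n_atoms, bonds) {
  in_ring <- rep(FALSE, n_atoms)
  if (nrow(bonds) == 0) return(in_ring)
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  cyc <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  ring_idx <- unique(c(bonds$i[cyc], bonds$j[cyc]))
  in_ring[ring_idx] <- TRUE
  in_ring
}

.mol_from_parsed <- function(parsed, smiles, radius_source,
                             table = element_table()) {
  el <- parsed$elements
  bonds <- parsed$bonds
  n <- length(el)
  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  atoms <- data.frame(
    element = el,
    degree = degree,
    radius = .element_property(el, radius_source, table),
    mass = .element_property(el, "mass", table),
    in_ring = .ring_atoms(n, bonds),
    stringsAsFactors = FALSE
  )
  structure(list(smiles = smiles, atoms = atoms, bonds = bonds,
                 conformer = NULL, energy_minimized = NA,
                 radius_source = radius_source),
            class = "ccs_molecule")
}

#' Parse a SMILES string into a molecule
#'
#' Interprets the SMILES with Open Babel, adds explicit hydrogens, perceives
#' aromaticity and ring membership, and records per-atom attributes (element,
#' degree, radius, mass, in-ring flag) and per-bond orders (single, double,
#' triple, aromatic). Heavy atoms keep their input order; hydrogens are
#' appended after them.
#'
#' @param smiles Non-empty SMILES string.
#' @param radius_source Which per-element radius fills the atom radius
#'   attribute: \code{"covalent_radius"} (default) or \code{"vdw_radius"}.
#' @param on_unsupported What to do when the molecule contains elements
#'   outside the supported 13: \code{"error"} (default) or \code{"warn"}.
#' @return A \code{ccs_molecule}: list with \code{smiles} (canonical),
#'   \code{atoms}, \code{bonds}, \code{conformer} (NULL until embedded).
#' @export
parse_molecule <- function(smiles,
                           radius_source = c("covalent_radius", "vdw_radius"),
                           on_unsupported = c("error", "warn")) {
  radius_source <- match.arg(radius_source)
  on_unsupported <- match.arg(on_unsupported)
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles))) {
    stop(errorCondition("SMILES must be a non-empty string",
                        class = c("graphccs_invalid_smiles", "graphccs_error")))
  }
  can <- suppressWarnings(try(.ob_convert(smiles, "SMI", "CAN"), silent = TRUE))
  if (inherits(can, "try-error") || !nzchar(trimws(can))) {
    stop(errorCondition(sprintf("cannot parse SMILES: '%s'", smiles),
                        class = c("graphccs_invalid_smiles", "graphccs_error")))
  }
  can <- strsplit(trimws(can), "[\t ]")[[1]][1]
  # build the structure from the canonical form so atom order is stable
  # across parsing and later conformer generation
  mol2 <- suppressWarnings(.ob_convert(can, "SMI", "MOL2", opts = "h"))
  parsed <- .parse_mol2(mol2)
  if (length(parsed) == 0) {
    stop(errorCondition(sprintf("cannot parse SMILES: '%s'", smiles),
                        class = c("graphccs_invalid_smiles", "graphccs_error")))
  }
  p <- parsed[[1]]
  known <- p$elements %in% element_table()$element
  if (!all(known)) {
    msg <- sprintf("unsupported element(s) in '%s': %s", smiles,
                   paste(unique(p$elements[!known]), collapse = ", "))
    if (on_unsupported == "error") {
      stop(errorCondition(msg, class = c("graphccs_unsupported_element",
                                         "graphccs_error")))
    }
    warning(msg)
    # near-zero radius/mass placeholders so the graph still builds
    tab <- rbind(element_table(),
                 data.frame(element = unique(p$elements[!known]),
                            mass = 1e-6, covalent_radius = 1e-6,
                            vdw_radius = 1e-6))
    return(.mol_from_parsed(p, can, radius_source, table = tab))
  }
  .mol_from_parsed(p, can, radius_source)
}

#' @export
print.ccs_molecule <- function(x, ...) {
  cat(sprintf("<ccs_molecule> %s\n  %d atoms (%d heavy), %d bonds, conformer: %s\n",
              x$smiles, nrow(x$atoms), sum(x$atoms$element != "H"),
              nrow(x$bonds),
              if (is.null(x$conformer)) "none" else "3D"))
  invisible(x)
}

.bonded_distances <- function(coords, bonds) {
  if (nrow(bonds) == 0) return(numeric(0))
  d <- coords[bonds$i, , drop = FALSE] - coords[bonds$j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Generate a 3D conformer for a molecule
#'
#' Embeds one conformer by distance geometry with experimental-torsion
#' knowledge (ETKDG) and minimises it with the MMFF94 force field (RDKit
#' backend). Deterministic for a fixed seed.
#'
#' @param mol A \code{ccs_molecule} from \code{\link{parse_molecule}}.
#' @param seed Integer seed for the distance-geometry embedding.
#' @return N x 3 coordinate matrix (Angstrom), one row per atom in the
#'   molecule's atom order, with attribute \code{energy_minimized}
#'   (\code{TRUE} when MMFF94 converged).
#' @export
generate_conformer <- function(mol, seed = 1L) {
  stopifnot(inherits(mol, "ccs_molecule"))
  res <- .rdkit_embed(mol$smiles, "m", seed = seed)[["m"]]
  if (is.null(res) || res$status == "parse_fail" ||
      res$status == "embed_fail" ||
      nrow(res$coords) != nrow(mol$atoms) ||
      !all(res$elements == mol$atoms$element)) {
    stop(errorCondition(
      sprintf("3D embedding failed for '%s'", mol$smiles),
      class = c("graphccs_embedding_failed", "graphccs_error")))
  }
  if (res$minimized < 0) {
    warning(sprintf("MMFF94 setup failed for '%s'; using raw embedding",
                    mol$smiles))
  }
  .validate_conformer(res$coords, mol, minimized = res$minimized)
}

.validate_conformer <- function(coords, mol, minimized = 1L) {
  if (!all(is.finite(coords)) ||
      (nrow(coords) > 1 && max(abs(coords)) < 1e-8)) {
    stop(errorCondition(
      sprintf("3D embedding produced degenerate coordinates for '%s'",
              mol$smiles),
      class = c("graphccs_embedding_failed", "graphccs_error")))
  }
  bd <- .bonded_distances(coords, mol$bonds)
  if (length(bd) && any(bd <= 0.1)) {
    stop(errorCondition(
      sprintf("force-field minimisation failed for '%s' (coincident bonded atoms)",
              mol$smiles),
      class = c("graphccs_minimization_failed", "graphccs_error")))
  }
  structure(coords, energy_minimized = minimized == 1L)
}

#' Embed one or many molecules, attaching conformers
#'
#' \code{embed_molecule} returns the molecule with its conformer attached;
#' \code{embed_molecules} embeds a list of molecules in a single batched
#' backend call (much faster than one call per molecule). Molecules that fail
#' embedding are returned unchanged (conformer stays NULL) when
#' \code{on_failure = "keep"}, or trigger an error when \code{"error"}.
#'
#' @param mol,mols Molecule / list of molecules.
#' @param seed Integer seed (see \code{\link{generate_conformer}}).
#' @param on_failure \code{"keep"} or \code{"error"}.
#' @return Updated molecule(s); each successful one has \code{$conformer}
#'   set and \code{$energy_minimized} filled.
#' @export
embed_molecule <- function(mol, seed = 1L) {
  conf <- generate_conformer(mol, seed)
  mol$conformer <- conf
  mol$energy_minimized <- attr(conf, "energy_minimized")
  mol
}

#' @rdname embed_molecule
#' @export
embed_molecules <- function(mols, seed = 1L, on_failure = c("keep", "error")) {
  on_failure <- match.arg(on_failure)
  if (length(mols) == 0) return(mols)
  tags <- sprintf("gccs%06d", seq_along(mols))
  parsed <- .rdkit_embed(vapply(mols, `[[`, "", "smiles"), tags,
                         seed = seed)
  for (k in seq_along(mols)) {
    p <- parsed[[tags[k]]]
    ok <- !is.null(p) && p$status == "ok" &&
      nrow(p$coords) == nrow(mols[[k]]$atoms) &&
      all(p$elements == mols[[k]]$atoms$element)
    if (ok) {
      conf <- try(.validate_conformer(p$coords, mols[[k]], p$minimized),
                  silent = TRUE)
      ok <- !inherits(conf, "try-error")
    }
    if (!ok) {
      if (on_failure == "error") {
        stop(errorCondition(
          sprintf("3D embedding failed for '%s'", mols[[k]]$smiles),
          class = c("graphccs_embedding_failed", "graphccs_error")))
      }
      next
    }
    mols[[k]]$conformer <- conf
    mols[[k]]$energy_minimized <- attr(conf, "energy_minimized")
  }
  mols
}

# ---- Tabular record I/O ----------------------------------------------------

.empty_records <- function() {
  data.frame(identifier = character(0), smiles = character(0),
             adduct = character(0), ccs = numeric(0), mz = numeric(0),
             rt = numeric(0), instrument = character(0),
             stringsAsFactors = FALSE)
}

.as_num <- function(x, what, path) {
  if (is.null(x)) return(NULL)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop(errorCondition(
      sprintf("%s: malformed %s value at data row %d ('%s')",
              path, what, bad[1], x[bad[1]]),
      class = c("graphccs_format_error", "graphccs_error")))
  }
  out
}

#' Read CCS records from CSV or SDF
#'
#' CSV files need header columns \code{smiles} and \code{adduct}
#' (case-insensitive); \code{ccs}, \code{mz}, \code{rt}, \code{identifier}
#' and \code{instrument} are optional. Missing CCS is allowed (prediction
#' mode). SDF files are read with ChemmineR; CCS / adduct / m/z / RT are
#' taken from identically named data-block properties when present.
#'
#' @param path File path.
#' @param format \code{"csv"} or \code{"sdf"}; default inferred from the
#'   file extension.
#' @return data.frame with columns identifier, smiles, adduct, ccs, mz, rt,
#'   instrument — one row per record, in file order.
#' @export
read_records <- function(path, format = c("auto", "csv", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  }
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("graphccs_format_error", "graphccs_error")))
  }
  if (format == "csv") .read_records_csv(path) else .read_records_sdf(path)
}

.read_records_csv <- function(path) {
  df <- try(utils::read.csv(path, stringsAsFactors = FALSE), silent = TRUE)
  if (inherits(df, "try-error")) {
    stop(errorCondition(sprintf("%s: cannot parse CSV", path),
                        class = c("graphccs_format_error", "graphccs_error")))
  }
  names(df) <- tolower(names(df))
  if (nrow(df) == 0) return(.empty_records())
  need <- c("smiles", "adduct")
  if (!all(need %in% names(df))) {
    stop(errorCondition(
      sprintf("%s: missing required column(s): %s", path,
              paste(setdiff(need, names(df)), collapse = ", ")),
      class = c("graphccs_format_error", "graphccs_error")))
  }
  n <- nrow(df)
  out <- data.frame(
    identifier = if ("identifier" %in% names(df)) as.character(df$identifier)
                 else sprintf("rec_%05d", seq_len(n)),
    smiles = as.character(df$smiles),
    adduct = as.character(df$adduct),
    ccs = if ("ccs" %in% names(df)) .as_num(df$ccs, "ccs", path) else NA_real_,
    mz = if ("mz" %in% names(df)) .as_num(df$mz, "mz", path) else NA_real_,
    rt = if ("rt" %in% names(df)) .as_num(df$rt, "rt", path) else NA_real_,
    instrument = if ("instrument" %in% names(df)) as.character(df$instrument)
                 else "unknown",
    stringsAsFactors = FALSE
  )
  # validate adducts here so the caller gets a row-addressed error
  chk <- vapply(out$adduct, function(a)
    !inherits(try(normalize_adduct(a), silent = TRUE), "try-error"),
    logical(1))
  if (!all(chk)) {
    stop(errorCondition(
      sprintf("%s: unknown adduct '%s' at data row %d", path,
              out$adduct[!chk][1], which(!chk)[1]),
      class = c("graphccs_unknown_adduct", "graphccs_error")))
  }
  out$adduct <- normalize_adduct(out$adduct)
  out
}

.read_records_sdf <- function(path) {
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  n <- length(sdf)
  if (n == 0) return(.empty_records())
  smi_out <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_out))
  ChemmineOB::convertFormatFile("SDF", "CAN", path, smi_out)
  smi <- vapply(strsplit(readLines(smi_out, warn = FALSE), "[\t ]"),
                `[[`, "", 1)
  if (length(smi) != n) {
    stop(errorCondition(sprintf("%s: cannot interpret all SDF records", path),
                        class = c("graphccs_format_error", "graphccs_error")))
  }
  get_prop <- function(blk, key) {
    hit <- which(tolower(names(blk)) == tolower(key))
    if (length(hit)) unname(blk[hit[1]]) else NA
  }
  rows <- lapply(seq_len(n), function(k) {
    blk <- ChemmineR::datablock(sdf[[k]])
    adduct <- get_prop(blk, "adduct")
    if (is.na(adduct)) adduct <- "[M+H]+"
    id <- get_prop(blk, "identifier")
    data.frame(
      identifier = if (is.na(id)) sprintf("rec_%05d", k) else
        as.character(id),
      smiles = smi[k],
      adduct = normalize_adduct(as.character(adduct)),
      ccs = suppressWarnings(as.numeric(get_prop(blk, "ccs"))),
      mz = suppressWarnings(as.numeric(get_prop(blk, "mz"))),
      rt = suppressWarnings(as.numeric(get_prop(blk, "rt"))),
      instrument = "unknown", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write prediction records to CSV
#'
#' One row per (molecule, adduct) with the predicted CCS in Angstrom^2.
#' Values are written at full precision; a read-back reproduces them to
#' well beyond 4 decimals.
#'
#' @param records data.frame with at least identifier, smiles, adduct and a
#'   prediction column (\code{ccs_pred} or \code{ccs}).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(records, path) {
  cols <- c("identifier", "smiles", "adduct")
  pred_col <- if ("ccs_pred" %in% names(records)) "ccs_pred" else "ccs"
  keep <- c(cols, pred_col, intersect(c("status", "above_ceiling"),
                                      names(records)))
  df <- records[, intersect(keep, names(records)), drop = FALSE]
  ok <- try(utils::write.csv(df, path, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(errorCondition(sprintf("cannot write predictions to %s", path),
                        class = c("graphccs_io_error", "graphccs_error")))
  }
  invisible(path)
}

#' Export a molecule's conformer as an SDF (V2000) file
#'
#' @param mol Molecule with a conformer.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_conformer_sdf <- function(mol, path) {
  stopifnot(inherits(mol, "ccs_molecule"), !is.null(mol$conformer))
  n <- nrow(mol$atoms); m <- nrow(mol$bonds)
  ord <- match(mol$bonds$order, .BOND_ORDERS)
  ord[ord == 4] <- 4L  # SDF aromatic code
  lines <- c(
    mol$smiles, "  graphccs 3D", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            mol$conformer[, 1], mol$conformer[, 2], mol$conformer[, 3],
            mol$atoms$element),
    if (m) sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j, ord),
    "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}
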