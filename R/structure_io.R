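#' Coarse-grained structure representation
#'
#' A `ca_structure` is a data frame with one row per residue and columns
#' `chain`, `seq_index` (1-based consecutive model index), `auth_resnum`
#' (author residue number), `insert` (insertion code, `""` if none), `aa`
#' (one-letter code), `ca_x/ca_y/ca_z` (Calpha coordinates, Angstrom) and
#' `sg_x/sg_y/sg_z` (cysteine SG coordinates, `NA` for non-cysteines or
#' disordered side chains). The structure identifier is kept in the
#' `source_id` attribute.
#'
#' @param df data frame with the columns listed above.
#' @param source_id character identifier for the structure.
#' @return A `ca_structure` object.
#' @export
ca_structure <- function(df, source_id = "unknown") {
  required <- c("chain", "seq_index", "auth_resnum", "aa",
                "ca_x", "ca_y", "ca_z")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("ca_structure is missing columns: ", paste(missing, collapse = ", "))
  if (!"insert" %in% names(df)) df$insert <- ""
  for (col in c("sg_x", "sg_y", "sg_z")) if (!col %in% names(df)) df[[col]] <- NA_real_
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  if (n == 0) stop("empty model: no residues with a Calpha atom")
  df$seq_index <- seq_len(n)
  if (!all(is.finite(as.matrix(df[, c("ca_x", "ca_y", "ca_z")]))))
    stop("non-finite Calpha coordinates")
  has_sg <- !is.na(df$sg_x)
  if (any(has_sg & df$aa != "C"))
    stop("sg coordinates present on a non-cysteine residue")
  attr(df, "source_id") <- source_id
  class(df) <- c("ca_structure", "data.frame")
  df
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("ca_structure '%s': %d residues, chains %s, %d cysteines with SG\n",
              attr(x, "source_id"), nrow(x),
              paste(unique(x$chain), collapse = ","),
              sum(!is.na(x$sg_x))))
  invisible(x)
}

#' Number of residues in a structure
#' @param x a `ca_structure`.
#' @return Integer residue count N.
#' @export
n_residues <- function(x) nrow(x)

#' Calpha coordinate matrix
#' @param x a `ca_structure`.
#' @return N x 3 numeric matrix of Calpha coordinates (Angstrom).
#' @export
ca_coords <- function(x) {
  m <- as.matrix(x[, c("ca_x", "ca_y", "ca_z")])
  dimnames(m) <- NULL
  m
}

#' One-letter sequence of a structure
#' @param x a `ca_structure`.
#' @return Character scalar, one letter per residue.
#' @export
ca_sequence <- function(x) paste(x$aa, collapse = "")

#' Read a structure file into the coarse-grained representation
#'
#' Parses a PDB or mmCIF file (model 1 only) and keeps, per residue, the
#' Calpha atom plus the SG atom of cysteines. Alternate locations are
#' resolved to the highest-occupancy copy; residues lacking a Calpha are
#' skipped with a warning. Residues are ordered by chain and author
#' numbering (insertion codes kept as distinct residues in file order) and
#' renumbered consecutively from 1.
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chains optional character vector of chain identifiers to keep.
#' @param source_id identifier stored on the result; defaults to the file
#'   base name.
#' @return A [ca_structure()].
#' @export
load_structure <- function(path, chains = NULL, source_id = NULL) {
  atoms <- read_atom_table(path)
  if (is.null(source_id))
    source_id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                     ignore.case = TRUE)
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  poly <- atoms[atoms$type == "ATOM", , drop = FALSE]
  ca <- pick_altloc(poly[poly$elety == "CA", , drop = FALSE])
  if (nrow(ca) == 0)
    stop("empty model: no polymer residues with a Calpha atom in ", path)
  sg <- pick_altloc(poly[poly$elety == "SG" & poly$resid == "CYS", , drop = FALSE])

  # residues that have polymer atoms but no Calpha (e.g. some modified
  # residues): report and drop
  key <- function(d) paste(d$chain, d$resno, d$insert, sep = "|")
  all_res <- unique(key(poly))
  lost <- setdiff(all_res, unique(key(ca)))
  if (length(lost) > 0)
    warning(sprintf("%d residue(s) without a Calpha skipped in %s",
                    length(lost), basename(path)))

  ord <- order(match(ca$chain, unique(ca$chain)), ca$resno,
               match(key(ca), unique(key(ca))))
  ca <- ca[ord, , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(ca$resid))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"

  df <- data.frame(chain = ca$chain, seq_index = seq_len(nrow(ca)),
                   auth_resnum = ca$resno, insert = ca$insert, aa = aa,
                   ca_x = ca$x, ca_y = ca$y, ca_z = ca$z,
                   sg_x = NA_real_, sg_y = NA_real_, sg_z = NA_real_,
                   stringsAsFactors = FALSE)
  if (nrow(sg) > 0) {
    df_key <- paste(df$chain, df$auth_resnum, df$insert, sep = "|")
    idx <- match(key(sg), df_key)
    ok <- !is.na(idx) & df$aa[idx] == "C"
    df$sg_x[idx[ok]] <- sg$x[ok]
    df$sg_y[idx[ok]] <- sg$y[ok]
    df$sg_z[idx[ok]] <- sg$z[ok]
  }
  ca_structure(df, source_id = source_id)
}

# Internal: normalized atom table (type, elety, alt, resid, chain, resno,
# insert, x, y, z, o, elesy) from a PDB or mmCIF file, model 1 only.
read_atom_table <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE),
    error = function(e) stop("cannot parse structure file ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  if (is.null(a$o)) a$o <- 1
  a$o[is.na(a$o)] <- 1
  a
}

# Internal: among duplicated (chain, resno, insert, elety) rows keep the
# highest occupancy (first in file order on ties).
pick_altloc <- function(a) {
  if (nrow(a) <= 1) return(a)
  k <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(match(k, unique(k)), -a$o)
  a <- a[ord, , drop = FALSE]
  a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "|")), ,
    drop = FALSE]
}

#' Extract iron sites from a structure file
#'
#' Returns one row per Fe atom found in hetero-groups whose residue name is
#' in `cluster_names` (cubane, [2Fe-2S], [3Fe-4S] and lone-iron groups by
#' default). Result order is independent of record order in the file.
#'
#' @param path structure file path.
#' @param cluster_names residue names treated as iron-bearing cofactors.
#' @return data frame with columns `fe_x`, `fe_y`, `fe_z`, `cluster_name`,
#'   `cluster_id`; zero rows when the structure has no such cofactor.
#' @export
extract_fe_sites <- function(path, cluster_names = c("SF4", "FES", "F3S", "FE")) {
  atoms <- read_atom_table(path)
  het <- atoms[atoms$type == "HETATM" & atoms$resid %in% cluster_names, ,
               drop = FALSE]
  is_fe <- toupper(ifelse(is.na(het$elesy) | het$elesy == "",
                          substr(het$elety, 1, 2), het$elesy)) == "FE"
  het <- het[is_fe, , drop = FALSE]
  if (nrow(het) == 0)
    return(data.frame(fe_x = numeric(0), fe_y = numeric(0), fe_z = numeric(0),
                      cluster_name = character(0), cluster_id = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(fe_x = het$x, fe_y = het$y, fe_z = het$z,
                    cluster_name = het$resid,
                    cluster_id = paste(het$resid, het$chain, het$resno,
                                       sep = "_"),
                    stringsAsFactors = FALSE)
  out[order(out$cluster_id, out$fe_x, out$fe_y, out$fe_z), , drop = FALSE]
}

#' Write a coarse-grained structure as a minimal PDB file
#'
#' Serializes Calpha (and cysteine SG) atoms as ATOM records and optional
#' iron sites as HETATM records, so fixtures can exercise the file-based
#' pipeline end to end. Not a general-purpose PDB writer.
#'
#' @param structure a [ca_structure()].
#' @param path output file path.
#' @param fe_sites optional data frame as returned by [extract_fe_sites()].
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(structure, path, fe_sites = NULL) {
  aa123 <- bio3d::aa123(structure$aa)
  aa123[structure$aa == "X"] <- "UNK"
  lines <- character(0)
  serial <- 0L
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  for (i in seq_len(nrow(structure))) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(fmt, "ATOM", serial, " CA ", "", aa123[i],
                              structure$chain[i], structure$auth_resnum[i],
                              substr(paste0(structure$insert[i], " "), 1, 1),
                              structure$ca_x[i], structure$ca_y[i],
                              structure$ca_z[i], 1, 0, "C"))
    if (!is.na(structure$sg_x[i])) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, "ATOM", serial, " SG ", "", aa123[i],
                                structure$chain[i], structure$auth_resnum[i],
                                substr(paste0(structure$insert[i], " "), 1, 1),
                                structure$sg_x[i], structure$sg_y[i],
                                structure$sg_z[i], 1, 0, "S"))
    }
  }
  if (!is.null(fe_sites) && nrow(fe_sites) > 0) {
    for (i in seq_len(nrow(fe_sites))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, "HETATM", serial, "FE  ", "",
                                substr(paste0(fe_sites$cluster_name[i], "  "), 1, 3),
                                "Z", 900L + i, " ",
                                fe_sites$fe_x[i], fe_sites$fe_y[i],
                                fe_sites$fe_z[i], 1, 0, "FE"))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a PyMOL script highlighting matched regions
#'
#' Emits one named selection and one color assignment per match, grouped by
#' island; re-running the script in a PyMOL session is harmless.
#'
#' @param matches data frame of match records as produced by
#'   [assemble_matches()] (needs columns `island_id`, `chain`, `auth_start`,
#'   `auth_end`).
#' @param path output `.pml` path.
#' @param object PyMOL object name the selections refer to (default `"target"`).
#' @return `path`, invisibly. An empty match list writes nothing and warns.
#' @export
write_pymol_script <- function(matches, path, object = "target") {
  if (is.null(matches) || nrow(matches) == 0) {
    warning("no matches to write; PyMOL script not created")
    return(invisible(NULL))
  }
  palette <- c("red", "orange", "yellow", "green", "cyan", "blue",
               "purple", "magenta", "salmon", "teal", "olive", "slate")
  islands <- unique(matches$island_id)
  col <- stats::setNames(palette[(seq_along(islands) - 1L) %% length(palette) + 1L],
                         islands)
  lines <- c("bg_color white", sprintf("hide everything, %s", object),
             sprintf("show cartoon, %s", object),
             sprintf("color grey80, %s", object))
  for (i in seq_len(nrow(matches))) {
    sel <- sprintf("match_%s_%d", matches$island_id[i], i)
    lines <- c(lines,
               sprintf("select %s, %s and chain %s and resi %d-%d",
                       sel, object, matches$chain[i],
                       matches$auth_start[i], matches$auth_end[i]),
               sprintf("color %s, %s", col[[matches$island_id[i]]], sel))
  }
  lines <- c(lines, "deselect")
  writeLines(lines, path)
  invisible(path)
}

#' Write a match table as tab-separated values
#'
#' @param matches data frame of match records ([assemble_matches()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(matches, path) {
  cols <- c("island_id", "length", "center", "chain", "auth_start", "auth_end",
            "s_cosine", "s_frobenius", "s_sw", "s_weighted")
  keep <- intersect(cols, names(matches))
  utils::write.table(matches[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
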