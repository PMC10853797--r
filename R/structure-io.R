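#' Write a model or trace to PDB or mmCIF
#'
#' Pseudoatom traces are written as one MG heteroatom per base pair (one
#' residue per ion, one chain per entry strand); all-atom models use
#' standard DNA residue names (DA/DC/DG/DT) and PDB v3 atom naming.
#' Coordinates are written in Angstrom (the package works in nm
#' internally). PDB is limited to 99,999 atoms; larger models must go to
#' mmCIF.
#'
#' @param x A \code{dna_model} or \code{spool_trace}.
#' @param path Output file path.
#' @param format "pdb" or "mmcif"; default guessed from the file
#'   extension (\code{.cif} / \code{.mmcif} = mmCIF, else PDB).
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(x, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  format <- match.arg(format, c("pdb", "mmcif"))
  at <- structure_atom_table(x)
  if (format == "pdb" && nrow(at) > 99999L)
    stop(paste("PDB cannot hold", nrow(at), "atoms (max 99999);",
               "use format = 'mmcif'"), call. = FALSE)
  hdr_note <- character()
  if (inherits(x, "dna_model") && isTRUE(x$default_sequence))
    hdr_note <- "default repeating AT sequence (none supplied)"
  if (format == "pdb") write_pdb_table(at, path, hdr_note)
  else write_mmcif_table(at, path, hdr_note)
  invisible(path)
}

# normalize either object to a flat atom table
structure_atom_table <- function(x) {
  if (inherits(x, "dna_model")) {
    at <- x$atoms
    data.frame(record = "ATOM", atom = at$atom, resname = at$resname,
               chain = at$chain, resid = at$resid, x = at$x, y = at$y,
               z = at$z, element = at$element, stringsAsFactors = FALSE)
  } else if (inherits(x, "spool_trace") || is.matrix(x)) {
    pts <- if (inherits(x, "spool_trace")) x$points else x
    entry <- if (inherits(x, "spool_trace")) x$entry else
      rep(0L, nrow(pts))
    chain_ids <- c(LETTERS, letters)
    resid <- stats::ave(seq_along(entry), entry, FUN = seq_along)
    data.frame(record = "HETATM", atom = "MG", resname = "MG",
               chain = chain_ids[(entry %% length(chain_ids)) + 1L],
               resid = as.integer(resid), x = pts[, 1], y = pts[, 2],
               z = pts[, 3], element = "MG", stringsAsFactors = FALSE)
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
}

pdb_atom_name <- function(atom, element) {
  # element right-justified in cols 13-14; 1-letter elements start col 14
  ifelse(nchar(element) >= 2L | nchar(atom) >= 4L,
         formatC(atom, width = -4),
         paste0(" ", formatC(atom, width = -3)))
}

write_pdb_table <- function(at, path, note = character()) {
  lines <- c("REMARK   1 WRITTEN BY DNASPOOL",
             if (length(note)) paste("REMARK   1", toupper(note)))
  serial <- seq_len(nrow(at))
  lines <- c(lines, sprintf(
    "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$record, ((serial - 1L) %% 99999L) + 1L,
    pdb_atom_name(at$atom, at$element), "",
    formatC(at$resname, width = 3), substr(at$chain, 1, 1),
    ((at$resid - 1L) %% 9999L) + 1L, "",
    at$x * 10, at$y * 10, at$z * 10, 1, 0,
    formatC(toupper(at$element), width = 2)))
  lines <- c(lines, "END")
  writeLines(lines, path)
}

cif_quote <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)

write_mmcif_table <- function(at, path, note = character()) {
  serial <- seq_len(nrow(at))
  lines <- c("data_dnaspool",
             "#",
             if (length(note)) c(paste("# note:", note), "#"),
             "loop_",
             "_atom_site.group_PDB",
             "_atom_site.id",
             "_atom_site.type_symbol",
             "_atom_site.label_atom_id",
             "_atom_site.label_alt_id",
             "_atom_site.label_comp_id",
             "_atom_site.label_asym_id",
             "_atom_site.label_entity_id",
             "_atom_site.label_seq_id",
             "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x",
             "_atom_site.Cartn_y",
             "_atom_site.Cartn_z",
             "_atom_site.occupancy",
             "_atom_site.B_iso_or_equiv",
             "_atom_site.auth_seq_id",
             "_atom_site.auth_asym_id",
             "_atom_site.pdbx_PDB_model_num",
             sprintf("%s %d %s %s . %s %s 1 %d ? %.6f %.6f %.6f 1.00 0.00 %d %s 1",
                     at$record, serial, toupper(at$element),
                     cif_quote(at$atom), at$resname, at$chain, at$resid,
                     at$x * 10, at$y * 10, at$z * 10, at$resid, at$chain),
             "#")
  writeLines(lines, path)
}

#' Read atoms from a PDB or mmCIF file
#'
#' Minimal reader for the structures this package writes (and
#' similarly-conventional files): returns a flat atom table in nm.
#'
#' @param path File path.
#' @param format "pdb" or "mmcif"; default guessed from the extension.
#' @return data.frame with columns \code{record}, \code{atom},
#'   \code{resname}, \code{chain}, \code{resid}, \code{x}, \code{y},
#'   \code{z} (nm), \code{element}.
#' @export
read_structure <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  format <- match.arg(format, c("pdb", "mmcif"))
  if (format == "pdb") read_pdb_atoms(path) else read_mmcif_atoms(path)
}

read_pdb_atoms <- function(path) {
  ln <- readLines(path)
  ln <- ln[startsWith(ln, "ATOM") | startsWith(ln, "HETATM")]
  f <- function(a, b) trimws(substr(ln, a, b))
  data.frame(record = f(1, 6), atom = f(13, 16), resname = f(18, 20),
             chain = f(22, 22), resid = as.integer(f(23, 26)),
             x = as.numeric(f(31, 38)) / 10,
             y = as.numeric(f(39, 46)) / 10,
             z = as.numeric(f(47, 54)) / 10,
             element = f(77, 78), stringsAsFactors = FALSE)
}

read_mmcif_atoms <- function(path) {
  ln <- readLines(path)
  loop_start <- which(ln == "loop_")
  as_start <- NA_integer_
  for (ls in loop_start) {
    if (ls < length(ln) && startsWith(ln[ls + 1L], "_atom_site."))
      { as_start <- ls; break }
  }
  if (is.na(as_start)) stop("no _atom_site loop in mmCIF", call. = FALSE)
  i <- as_start + 1L
  fields <- character()
  while (i <= length(ln) && startsWith(ln[i], "_atom_site.")) {
    fields <- c(fields, sub("^_atom_site\\.", "", trimws(ln[i])))
    i <- i + 1L
  }
  rows <- character()
  while (i <= length(ln) && !startsWith(ln[i], "#") &&
         !startsWith(ln[i], "loop_") && nzchar(trimws(ln[i]))) {
    rows <- c(rows, ln[i]); i <- i + 1L
  }
  toks <- lapply(rows, cif_tokens)
  if (!all(lengths(toks) == length(fields)))
    stop("malformed _atom_site loop: token/field count mismatch",
         call. = FALSE)
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  g <- function(nm) if (nm %in% fields) m[, nm] else NA
  data.frame(record = g("group_PDB"), atom = g("label_atom_id"),
             resname = g("label_comp_id"), chain = g("label_asym_id"),
             resid = as.integer(g("auth_seq_id")),
             x = as.numeric(g("Cartn_x")) / 10,
             y = as.numeric(g("Cartn_y")) / 10,
             z = as.numeric(g("Cartn_z")) / 10,
             element = g("type_symbol"), stringsAsFactors = FALSE)
}

# whitespace tokenizer honoring single/double quotes
cif_tokens <- function(line) {
  out <- character()
  rest <- trimws(line)
  while (nzchar(rest)) {
    q <- substr(rest, 1, 1)
    if (q %in% c("'", '"')) {
      end <- regexpr(paste0(q, "( |$)"), substr(rest, 2, nchar(rest)))
      tok <- substr(rest, 2, end)
      rest <- trimws(substr(rest, end + 2, nchar(rest)))
    } else {
      sp <- regexpr("[ \t]", rest)
      if (sp == -1) { tok <- rest; rest <- "" }
      else { tok <- substr(rest, 1, sp - 1)
             rest <- trimws(substr(rest, sp + 1, nchar(rest))) }
    }
    out <- c(out, tok)
  }
  out
}
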