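#' Idealized Watson-Crick base-pair template
#'
#' Loads the all-atom template used for coarse-to-fine model building: one
#' Watson-Crick base pair per strand-A base identity (A, C, G, T), heavy
#' atoms only, standard PDB v3 naming, in a pair-local frame with the
#' origin on the helix axis at the pair center, z along the helix axis and
#' y along the in-plane component of the C1' (strand A) to C1' (strand B)
#' direction. The packaged template was derived from an idealized B-form
#' DNA fiber-diffraction model (see the file header for provenance) and is
#' stored as plain text.
#'
#' @param path Path to a template file; defaults to the packaged one.
#' @return An object of class \code{"bp_template"}: a list of four
#'   data.frames keyed by the strand-A base, each with columns
#'   \code{strand} (A/B), \code{resname}, \code{atom}, \code{element},
#'   \code{x}, \code{y}, \code{z} (nm); attributes \code{c1c1} (the fixed
#'   C1'-C1' distance, nm), \code{rise} and \code{twist} (the stacking
#'   step of the underlying fiber model) and \code{o3p_ref} (named vector
#'   over strands A and B: the O3'-P inter-residue bond length when two
#'   template pairs are stacked at that rise and twist, nm).
#' @export
load_bp_template <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bdna_pair_template.txt",
                        package = "dnaspool", mustWork = TRUE)
  header <- readLines(path, n = 40L)
  header <- header[startsWith(header, "#")]
  meta <- function(key, default = NA_real_) {
    ln <- grep(paste0("^# ", key, " = "), header, value = TRUE)
    if (length(ln)) as.numeric(sub(".* = ", "", ln[1])) else default
  }
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("pair", "strand", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("template file must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  tmpl <- split(df[setdiff(names(df), "pair")], df$pair)
  if (!all(c("A", "C", "G", "T") %in% names(tmpl)))
    stop("template must define pairs for strand-A bases A, C, G, T",
         call. = FALSE)
  rise <- meta("rise_nm", 0.338)
  twist <- meta("twist_deg", 36)
  c1 <- vapply(tmpl, function(d) {
    a <- unlist(d[d$atom == "C1'" & d$strand == "A", c("x", "y", "z")])
    b <- unlist(d[d$atom == "C1'" & d$strand == "B", c("x", "y", "z")])
    sqrt(sum((a - b)^2))
  }, numeric(1))
  out <- structure(tmpl, class = "bp_template",
                   c1c1 = unname(mean(c1)), rise = rise, twist = twist)
  attr(out, "o3p_ref") <- template_stacked_o3p(out)
  out
}

# O3'(i) -> P(i+1) distance along strand A when two template pairs are
# stacked straight at the given rise and twist (defaults: the template's
# own step). Used as the strain-free reference, so the strain report
# isolates bending effects rather than the rise convention.
template_stacked_o3p <- function(tmpl, rise = attr(tmpl, "rise"),
                                 twist = attr(tmpl, "twist")) {
  d <- tmpl[["A"]]
  loc <- function(strand, atom)
    unlist(d[d$atom == atom & d$strand == strand, c("x", "y", "z")])
  Rz <- rotation_about_axis(c(0, 0, 1), twist * pi / 180)
  up <- c(0, 0, rise)
  # strand A runs 5'->3' with the stacking step; strand B against it
  c(A = sqrt(sum((loc("A", "O3'") -
                    (as.numeric(Rz %*% loc("A", "P")) + up))^2)),
    B = sqrt(sum((as.numeric(Rz %*% loc("B", "O3'")) + up -
                    loc("B", "P"))^2)))
}

#' @export
print.bp_template <- function(x, ...) {
  cat(sprintf(paste0("<bp_template: %d pairs, C1'-C1' = %.4f nm, ",
                     "stacked O3'-P = %.4f nm>\n"),
              length(x), attr(x, "c1c1"), mean(attr(x, "o3p_ref"))))
  invisible(x)
}

complement_base <- c(A = "T", T = "A", G = "C", C = "G")

# unit tangents along an ordered point path: central differences,
# one-sided at the ends
path_tangents <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(matrix(c(0, 0, 1), 1L, 3L))  # isolated bp: +z
  d <- matrix(0, n, 3)
  d[1, ] <- pts[2, ] - pts[1, ]
  d[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2L) d[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12))
    stop("coincident consecutive trace points: tangent undefined",
         call. = FALSE)
  d / len
}

# Rotation-minimizing frames by the double-reflection method
# (Wang, Juettler, Zheng & Liu 2008). Returns list(tangent, normal):
# n x 3 matrices; normal is transported with zero twist. Naive Frenet
# frames flip at inflection points, injecting spurious twist; RMF does not.
rm_frames <- function(pts) {
  t <- path_tangents(pts)
  n <- nrow(pts)
  u <- matrix(0, n, 3)
  # initial normal: the curvature direction at the leading end (covariant
  # with the curve, so models on rigidly transformed traces are related by
  # the same transform); for straight starts, fall back to the world axis
  # least aligned with the tangent (twist phase is then a convention)
  u0 <- c(0, 0, 0)
  if (n >= 3L) {
    cv <- pts[1, ] - 2 * pts[2, ] + pts[3, ]
    u0 <- cv - sum(cv * t[1, ]) * t[1, ]
  }
  if (sum(u0^2) < 1e-18) {
    seedv <- diag(3)[, which.min(abs(t[1, ]))]
    u0 <- seedv - sum(seedv * t[1, ]) * t[1, ]
  }
  u[1, ] <- u0 / sqrt(sum(u0^2))
  if (n == 1L) return(list(tangent = t, normal = u))
  for (i in seq_len(n - 1L)) {
    v1 <- pts[i + 1L, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    uL <- u[i, ] - (2 / c1) * sum(v1 * u[i, ]) * v1
    tL <- t[i, ] - (2 / c1) * sum(v1 * t[i, ]) * v1
    v2 <- t[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    u[i + 1L, ] <- if (c2 < 1e-24) uL else uL - (2 / c2) * sum(v2 * uL) * v2
  }
  list(tangent = t, normal = u)
}

#' Build an all-atom B-DNA duplex on a coarse trace
#'
#' Upgrades a pseudoatom trace to an all-atom double-stranded DNA model by
#' rigid-body placement of the idealized base-pair template: base pair i
#' is the template transformed so its origin lies at trace point i, its
#' z-axis along the local curve tangent, and its in-plane orientation
#' given by a rotation-minimizing frame advanced by \code{twist_per_bp}
#' per step. Because placement is rigid, inter-residue backbone bonds are
#' compressed on the inside of a curved trace and extended on the outside;
#' \code{\link{bond_strain_report}} quantifies this.
#'
#' Each entry strand of the trace becomes one duplex segment with two
#' antiparallel chains: chain A runs 5' to 3' in trace order, chain B
#' antiparallel. Segment k (0-based) uses chain IDs at positions 2k+1 and
#' 2k+2 of \code{LETTERS} followed by \code{letters}.
#'
#' @param trace A \code{spool_trace} (or N x 3 matrix of points, nm).
#' @param sequence Strand-A base sequence, a string over A/C/G/T of length
#'   equal to the number of trace points, or \code{NULL} for a repeating
#'   AT alternation (flagged in output headers).
#' @param twist_per_bp Helical twist per base-pair step, degrees
#'   (default 36, the 10 bp/turn B-DNA value).
#' @param template A \code{\link{load_bp_template}} result, or \code{NULL}
#'   for the packaged template.
#' @return An object of class \code{"dna_model"}: list with \code{atoms}
#'   (data.frame: segment, chain, strand, resid, resname, atom, element,
#'   x, y, z in nm), \code{bp_centers} (the input trace points),
#'   \code{sequence}, \code{twist_per_bp}, \code{template_ref} (template
#'   constants), \code{default_sequence} flag.
#' @export
build_duplex <- function(trace, sequence = NULL, twist_per_bp = 36,
                         template = NULL) {
  pts <- if (inherits(trace, "spool_trace")) trace$points else
    if (is.null(dim(trace))) matrix(trace, ncol = 3L) else trace
  entry <- if (inherits(trace, "spool_trace")) trace$entry else
    rep(0L, nrow(pts))
  if (is.null(template)) template <- load_bp_template()
  n <- nrow(pts)
  default_seq <- is.null(sequence)
  if (default_seq)
    sequence <- paste(rep_len(c("A", "T"), n), collapse = "")
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) != n)
    stop(sprintf("sequence length (%d) must equal trace point count (%d)",
                 length(bases), n), call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("sequence must contain only A, C, G, T", call. = FALSE)
  chain_ids <- c(LETTERS, letters)
  segs <- unique(entry)
  atom_tabs <- vector("list", 0L)
  for (si in seq_along(segs)) {
    sel <- which(entry == segs[si])
    p_seg <- pts[sel, , drop = FALSE]
    b_seg <- bases[sel]
    m <- length(sel)
    fr <- rm_frames(p_seg)
    ids <- chain_ids[((si - 1L) * 2L) %% length(chain_ids) + 1:2]
    for (i in seq_len(m)) {
      tv <- fr$tangent[i, ]
      yv <- as.numeric(rotation_about_axis(tv, (i - 1) * twist_per_bp *
                                             pi / 180) %*% fr$normal[i, ])
      xv <- c(yv[2] * tv[3] - yv[3] * tv[2],
              yv[3] * tv[1] - yv[1] * tv[3],
              yv[1] * tv[2] - yv[2] * tv[1])
      R <- cbind(xv, yv, tv)
      tp <- template[[b_seg[i]]]
      xyz <- as.matrix(tp[, c("x", "y", "z")]) %*% t(R)
      xyz <- sweep(xyz, 2, p_seg[i, ], "+")
      atom_tabs[[length(atom_tabs) + 1L]] <- data.frame(
        segment = si - 1L,
        chain = ifelse(tp$strand == "A", ids[1], ids[2]),
        strand = tp$strand,
        resid = ifelse(tp$strand == "A", i, m - i + 1L),
        resname = tp$resname,
        atom = tp$atom,
        element = tp$element,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, atom_tabs)
  atoms <- atoms[order(atoms$segment, atoms$strand, atoms$resid), ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bp_centers = pts, entry = entry,
                 sequence = paste(bases, collapse = ""),
                 twist_per_bp = twist_per_bp,
                 template_ref = list(
                   c1c1 = attr(template, "c1c1"),
                   # strain-free O3'-P at this model's own step: a straight
                   # duplex at the observed bp spacing and requested twist
                   o3p_ref = template_stacked_o3p(
                     template,
                     rise = if (n > 1L)
                       stats::median(sqrt(rowSums(
                         (pts[-1, , drop = FALSE] -
                          pts[-n, , drop = FALSE])^2))) else
                       attr(template, "rise"),
                     twist = twist_per_bp),
                   rise = attr(template, "rise"),
                   twist = attr(template, "twist")),
                 default_sequence = default_seq),
            class = "dna_model")
}

#' @export
print.dna_model <- function(x, ...) {
  cat(sprintf(
    "<dna_model: %d bp in %d segment(s), %d atoms, twist %.1f deg/bp>\n",
    nrow(x$bp_centers), length(unique(x$atoms$segment)), nrow(x$atoms),
    x$twist_per_bp))
  invisible(x)
}

#' Backbone bond-strain report
#'
#' Lists every inter-residue O3'-P backbone distance of the model with its
#' deviation from a strain-free reference. Rigid-body placement of base
#' pairs along a curved trace compresses these bonds on the inside of the
#' curve and extends them on the outside; this report is the diagnostic
#' replacement for a force-field bond annealing step.
#'
#' @param model A \code{\link{build_duplex}} result.
#' @param reference_length Strain-free O3'-P length, nm. Default: the
#'   template's value when stacked as a straight duplex at the model's own
#'   base-pair spacing and twist, so the report isolates bending strain.
#' @return data.frame of class \code{"strain_report"} with columns
#'   \code{segment}, \code{chain}, \code{resid_from}, \code{resid_to},
#'   \code{length}, \code{deviation} (nm); attributes \code{max_abs},
#'   \code{mean_abs}, \code{n_skipped} (bonds skipped for missing
#'   backbone atoms), \code{reference_length}.
#' @export
bond_strain_report <- function(model, reference_length = NULL) {
  stopifnot(inherits(model, "dna_model"))
  ref <- if (is.null(reference_length)) model$template_ref$o3p_ref else
    c(A = reference_length, B = reference_length)
  at <- model$atoms
  rows <- list()
  skipped <- 0L
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch, ]
    strand <- a$strand[1]
    resids <- sort(unique(a$resid))
    for (i in seq_len(length(resids) - 1L)) {
      o3 <- a[a$resid == resids[i] & a$atom == "O3'", c("x", "y", "z")]
      p <- a[a$resid == resids[i + 1L] & a$atom == "P", c("x", "y", "z")]
      if (nrow(o3) != 1L || nrow(p) != 1L) { skipped <- skipped + 1L; next }
      len <- sqrt(sum((unlist(o3) - unlist(p))^2))
      rows[[length(rows) + 1L]] <- data.frame(
        segment = a$segment[1], chain = ch,
        resid_from = resids[i], resid_to = resids[i + 1L],
        length = len, deviation = len - ref[[strand]])
    }
  }
  rep_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment = integer(), chain = character(),
               resid_from = integer(), resid_to = integer(),
               length = numeric(), deviation = numeric())
  structure(rep_df,
            max_abs = if (nrow(rep_df)) max(abs(rep_df$deviation)) else
              NA_real_,
            mean_abs = if (nrow(rep_df)) mean(abs(rep_df$deviation)) else
              NA_real_,
            n_skipped = skipped, reference_length = unname(mean(ref)),
            class = c("strain_report", "data.frame"))
}

#' @export
print.strain_report <- function(x, ...) {
  cat(sprintf(
    "<strain_report: %d bonds (ref %.4f nm), max |dev| %.4g, mean |dev| %.4g nm, %d skipped>\n",
    nrow(x), attr(x, "reference_length"),
    attr(x, "max_abs"), attr(x, "mean_abs"), attr(x, "n_skipped")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Read a DNA sequence from a FASTA file
#'
#' Minimal single-record FASTA reader for supplying a genome sequence to
#' \code{\link{build_duplex}}. Concatenates all sequence lines of the
#' first record; upper-cases; validates the A/C/G/T alphabet.
#'
#' @param path FASTA file path.
#' @return Character scalar sequence.
#' @export
read_fasta_sequence <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln) || !startsWith(ln[1], ">"))
    stop("not a FASTA file: missing '>' header", call. = FALSE)
  hdr <- which(startsWith(ln, ">"))
  end <- if (length(hdr) > 1L) hdr[2] - 1L else length(ln)
  seq <- toupper(paste(ln[2:end], collapse = ""))
  seq <- gsub("[[:space:]]", "", seq)
  if (!grepl("^[ACGT]+$", seq))
    stop("sequence must contain only A, C, G, T", call. = FALSE)
  seq
}
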