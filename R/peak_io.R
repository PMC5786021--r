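# Reading/writing assigned methyl peak lists and assembling multi-variant panels.
#
# A "peak table" is a data.frame with columns:
#   residue_number, residue_class, methyl_position, variant, delta_C, delta_H
# plus a derived canonical label column `methyl` (e.g. "I131-d1").
# residue_class is one of Ile/Leu/Val/Met; methyl_position uses ASCII labels
# d1 (Ile delta1), d/d1/d2 (Leu delta), g/g1/g2 (Val gamma), e (Met epsilon).

.methyl_classes <- c("Ile", "Leu", "Val", "Met")

.allowed_positions <- list(
  Ile = "d1",
  Leu = c("d", "d1", "d2"),
  Val = c("g", "g1", "g2"),
  Met = "e"
)

.class_letter <- c(Ile = "I", Leu = "L", Val = "V", Met = "M")

# Sparky atom-name <-> position label maps, per residue class
.sparky_atom_to_pos <- list(
  Ile = c(CD1 = "d1"),
  Leu = c(CD = "d", CD1 = "d1", CD2 = "d2"),
  Val = c(CG = "g", CG1 = "g1", CG2 = "g2"),
  Met = c(CE = "e")
)

#' Canonical methyl probe labels
#'
#' Builds the canonical label used throughout the package to identify a
#' side-chain methyl probe, e.g. `"I131-d1"` for Ile131 delta-1 or `"L800-d2"`
#' for the Leu800 delta-2 stereo partner.
#'
#' @param residue_number Integer residue number (construct numbering, taken
#'   verbatim from the input file).
#' @param residue_class One of `"Ile"`, `"Leu"`, `"Val"`, `"Met"`.
#' @param methyl_position Position label: `"d1"` (Ile), `"d"`/`"d1"`/`"d2"`
#'   (Leu), `"g"`/`"g1"`/`"g2"` (Val), `"e"` (Met).
#' @return Character vector of labels.
#' @examples
#' methyl_label(131, "Ile", "d1")
#' @export
methyl_label <- function(residue_number, residue_class, methyl_position) {
  check_methyl_id(residue_number, residue_class, methyl_position)
  paste0(.class_letter[residue_class], residue_number, "-", methyl_position)
}

#' Validate methyl identifiers
#'
#' Checks that the residue class is known and that the methyl position is
#' allowed for that class (the class determines the chemically possible
#' methyl positions).
#'
#' @inheritParams methyl_label
#' @return Invisibly `TRUE`; stops on invalid input.
#' @export
check_methyl_id <- function(residue_number, residue_class, methyl_position) {
  if (any(is.na(residue_number)) || any(residue_number != round(residue_number)))
    stop("residue_number must be whole numbers")
  bad_class <- setdiff(unique(residue_class), .methyl_classes)
  if (length(bad_class))
    stop("unknown residue class: ", paste(bad_class, collapse = ", "))
  ok <- mapply(function(cl, pos) pos %in% .allowed_positions[[cl]],
               residue_class, methyl_position)
  if (!all(ok)) {
    bad <- paste0(residue_class[!ok], "/", methyl_position[!ok])
    stop("methyl_position not allowed for residue class: ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

.finalize_peaks <- function(df, source = "peak list") {
  df$residue_number <- as.integer(df$residue_number)
  df$delta_C <- as.numeric(df$delta_C)
  df$delta_H <- as.numeric(df$delta_H)
  check_methyl_id(df$residue_number, df$residue_class, df$methyl_position)
  if (any(!is.finite(df$delta_C)) || any(!is.finite(df$delta_H)))
    stop(source, ": non-finite chemical shifts")
  out_c <- df$delta_C < -5 | df$delta_C > 35
  out_h <- df$delta_H < -2 | df$delta_H > 3
  if (any(out_c | out_h))
    warning(sum(out_c | out_h), " peak(s) outside plausible methyl ppm windows ",
            "(13C [-5, 35], 1H [-2, 3])")
  df$methyl <- methyl_label(df$residue_number, df$residue_class, df$methyl_position)
  key <- paste(df$methyl, df$variant)
  if (anyDuplicated(key)) {
    dups <- unique(df$methyl[duplicated(key)])
    stop(source, ": duplicate methyl entries: ", paste(dups, collapse = ", "))
  }
  rownames(df) <- NULL
  df[, c("methyl", "residue_number", "residue_class", "methyl_position",
         "variant", "delta_C", "delta_H")]
}

#' Parse a Sparky-style methyl assignment string
#'
#' Decodes strings such as `"I131CD1-HD1"` into residue number, residue class
#' and methyl position. Only ILVM methyl carbons are recognised
#' (Ile CD1; Leu CD/CD1/CD2; Val CG/CG1/CG2; Met CE).
#'
#' @param x Character vector of assignment strings.
#' @return A data.frame with columns `residue_number`, `residue_class`,
#'   `methyl_position`; unparseable entries yield `NA` rows.
#' @export
parse_sparky_assignment <- function(x) {
  m <- regmatches(x, regexec("^([ILVM])(\\d+)(C[DGE][12]?)(-H[DGE][12]?)?$",
                             toupper(trimws(x))))
  out <- data.frame(residue_number = rep(NA_integer_, length(x)),
                    residue_class = NA_character_,
                    methyl_position = NA_character_)
  letters_map <- setNames(names(.class_letter), .class_letter)
  for (i in seq_along(m)) {
    mi <- m[[i]]
    if (length(mi) == 0) next
    cl <- letters_map[[mi[2]]]
    pos_map <- .sparky_atom_to_pos[[cl]]
    atom <- mi[4]
    if (!atom %in% names(pos_map)) next
    out$residue_number[i] <- as.integer(mi[3])
    out$residue_class[i] <- cl
    out$methyl_position[i] <- unname(pos_map[[atom]])
  }
  out
}

#' Read an assigned methyl peak list
#'
#' Reads either a Sparky-style whitespace-delimited list
#' (`Assignment  w1  w2`, with w1 the 13C shift and w2 the 1H shift, both in
#' ppm) or a generic CSV with header columns `residue_number`,
#' `residue_class`, `methyl_position`, `delta_C`, `delta_H` and optionally
#' `variant`. Chemical shifts outside plausible methyl windows
#' (13C in \[-5, 35\] ppm, 1H in \[-2, 3\] ppm) raise a warning, not an error.
#'
#' @param path Path to the peak list file.
#' @param dialect `"sparky"`, `"csv"`, or `"auto"` (default; guessed from the
#'   file extension and first line).
#' @param variant Variant label to attach to every peak (e.g. `"WT"`,
#'   `"V156M"`). Overrides any `variant` column present in a CSV.
#' @return A peak table (see [build_panel()]).
#' @export
read_peaklist <- function(path, dialect = c("auto", "sparky", "csv"),
                          variant = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (grepl(",", first)) "csv" else "sparky"
  }
  if (dialect == "sparky") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) &
                    !grepl("^\\s*(#|Assignment)", lines, ignore.case = TRUE))
    if (!length(keep)) stop("no parseable rows in ", path)
    fields <- strsplit(trimws(lines[keep]), "\\s+")
    n_ok <- lengths(fields) >= 3
    ids <- parse_sparky_assignment(vapply(fields, `[`, "", 1L))
    parseable <- n_ok & !is.na(ids$residue_number)
    if (any(!parseable))
      warning("unparseable assignment rows at line(s): ",
              paste(keep[!parseable], collapse = ", "))
    if (!any(parseable)) stop("no parseable rows in ", path)
    df <- data.frame(
      residue_number = ids$residue_number[parseable],
      residue_class = ids$residue_class[parseable],
      methyl_position = ids$methyl_position[parseable],
      variant = if (is.null(variant)) NA_character_ else variant,
      delta_C = as.numeric(vapply(fields[parseable], `[`, "", 2L)),
      delta_H = as.numeric(vapply(fields[parseable], `[`, "", 3L))
    )
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    needed <- c("residue_number", "residue_class", "methyl_position",
                "delta_C", "delta_H")
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols))
      stop("CSV peak list missing column(s): ",
           paste(missing_cols, collapse = ", "))
    if (!nrow(df)) stop("no parseable rows in ", path)
    if (!is.null(variant)) df$variant <- variant
    if (is.null(df$variant)) df$variant <- NA_character_
  }
  .finalize_peaks(df, source = path)
}

#' Write a peak table
#'
#' Writes the canonical CSV dialect (all identifier columns plus shifts) or a
#' Sparky-style whitespace list. Both round-trip through [read_peaklist()].
#'
#' @param peaks A peak table.
#' @param path Output path.
#' @param dialect `"csv"` (canonical, default) or `"sparky"`.
#' @return Invisibly `path`.
#' @export
write_peaklist <- function(peaks, path, dialect = c("csv", "sparky")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    write.csv(peaks[, c("residue_number", "residue_class", "methyl_position",
                        "variant", "delta_C", "delta_H")],
              path, row.names = FALSE, quote = FALSE)
  } else {
    atom_rev <- lapply(.sparky_atom_to_pos, function(m) setNames(names(m), m))
    carbon <- mapply(function(cl, pos) atom_rev[[cl]][[pos]],
                     peaks$residue_class, peaks$methyl_position)
    proton <- sub("^C", "H", carbon)
    assignment <- paste0(.class_letter[peaks$residue_class],
                         peaks$residue_number, carbon, "-", proton)
    writeLines(c(sprintf("%-20s %9s %9s", "Assignment", "w1", "w2"),
                 sprintf("%-20s %9.3f %9.3f", assignment,
                         peaks$delta_C, peaks$delta_H)), path)
  }
  invisible(path)
}

#' Assemble a multi-variant peak panel
#'
#' Combines per-variant peak tables into the panel object consumed by the
#' chemical shift perturbation (CSP), covariance clustering and correlation
#' stages. Peaks are matched across variants by assignment label only; no
#' nearest-neighbour matching is attempted. With `require_complete = TRUE`
#' (default) only methyls observed in every variant are retained -- this also
#' removes mutated residues whose own peak disappears in their mutant (e.g.
#' the V156 peak in a V156M variant).
#'
#' @param peaklists Either a named list of peak tables (names = variant
#'   labels) or a single long peak table with a filled `variant` column.
#' @param reference_variant Reference (unperturbed) variant label, default
#'   `"WT"`.
#' @param require_complete Keep only methyls present in all variants
#'   (default `TRUE`); dropped methyls are reported via a message.
#' @return An object of class `variant_panel`: a list with elements `peaks`
#'   (long peak table), `variants` (ordered labels) and `reference_variant`.
#' @export
build_panel <- function(peaklists, reference_variant = "WT",
                        require_complete = TRUE) {
  if (is.data.frame(peaklists)) {
    long <- peaklists
  } else {
    stopifnot(is.list(peaklists))
    if (is.null(names(peaklists)) || any(!nzchar(names(peaklists))))
      stop("peaklists list must be named by variant")
    long <- do.call(rbind, lapply(names(peaklists), function(v) {
      df <- peaklists[[v]]
      df$variant <- v
      df
    }))
  }
  long <- .finalize_peaks(long, source = "panel")
  variants <- unique(long$variant)
  if (length(variants) < 2) stop("need at least 2 variants")
  if (!reference_variant %in% variants)
    stop("reference variant '", reference_variant, "' absent from panel")
  variants <- c(reference_variant, setdiff(variants, reference_variant))
  per_var <- split(long$methyl, long$variant)
  shared <- Reduce(intersect, per_var)
  if (!length(shared)) stop("zero methyls shared across variants")
  if (require_complete) {
    dropped <- setdiff(unique(long$methyl), shared)
    if (length(dropped))
      message("build_panel: dropped ", length(dropped),
              " methyl(s) not observed in all variants: ",
              paste(sort(dropped), collapse = ", "))
    long <- long[long$methyl %in% shared, , drop = FALSE]
  }
  long <- long[order(match(long$variant, variants), long$residue_number,
                     long$methyl_position), , drop = FALSE]
  rownames(long) <- NULL
  structure(list(peaks = long, variants = variants,
                 reference_variant = reference_variant),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("Methyl variant panel:", length(unique(x$peaks$methyl)), "methyls x",
      length(x$variants), "variants (", paste(x$variants, collapse = ", "),
      "), reference:", x$reference_variant, "\n")
  invisible(x)
}
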