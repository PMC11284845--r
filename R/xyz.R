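# Multi-frame XYZ input/output with comment-line energy parsing.

.num_re <- "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?"

# Returns list(value, unit or NA, rest-of-comment) or NULL when no energy
# expression is present.
.extract_energy <- function(comment) {
  txt <- trimws(comment)
  if (!nzchar(txt)) return(NULL)
  # dialects: "Energy= X", "E = X" (case-insensitive keyword)
  kw <- regexpr(sprintf("(?i)\\b(energy|e)\\s*=\\s*(%s)", .num_re), txt,
                perl = TRUE)
  if (kw[1L] > 0) {
    m <- regmatches(txt, kw)
    val <- regmatches(m, regexpr(.num_re, m))
    rest <- trimws(sub(m, "", txt, fixed = TRUE))
  } else {
    # bare leading number: first whitespace token is numeric
    tok <- strsplit(txt, "\\s+")[[1L]]
    if (!grepl(sprintf("^%s$", .num_re), tok[1L])) return(NULL)
    val <- tok[1L]
    rest <- tok[-1L]
    unit <- NA_character_
    if (length(rest) >= 1L &&
        tolower(rest[1L]) %in% c("hartree", "eh", "au", "kcal/mol", "kcal")) {
      unit <- tolower(rest[1L])
      rest <- rest[-1L]
    }
    return(list(value = as.numeric(val), unit = unit,
                rest = paste(rest, collapse = " ")))
  }
  # unit suffix directly after a keyword-dialect number
  unit <- NA_character_
  um <- regexpr("(?i)^(hartree|eh|au|kcal/mol|kcal)\\b", rest, perl = TRUE)
  if (um[1L] > 0) {
    unit <- tolower(regmatches(rest, um))
    rest <- trimws(sub("(?i)^(hartree|eh|au|kcal/mol|kcal)\\b", "", rest,
                       perl = TRUE))
  }
  list(value = as.numeric(val), unit = unit, rest = rest)
}

#' Parse an energy from an XYZ comment line
#'
#' Recognizes a bare leading number, `Energy= X` and `E = X` dialects, with
#' an optional unit token (`hartree`/`Eh`/`au` or `kcal/mol`). Under
#' `energy_unit = "auto"` a value with `|X| > 100` is interpreted as Hartree
#' and converted to kcal/mol (TS free energies on relative scales are small;
#' absolute electronic energies are hundreds of Hartree); an explicit unit
#' token or `energy_unit` overrides the heuristic.
#'
#' @param comment The comment line text.
#' @param energy_unit `"auto"`, `"kcal/mol"` or `"hartree"`.
#' @return Energy in kcal/mol, or `NA` when no number is found.
#' @export
#' @examples
#' parse_comment_energy("13.4")              # kcal/mol
#' parse_comment_energy("-460.5")            # Hartree, converted
#' parse_comment_energy("conformer 7")       # NA
parse_comment_energy <- function(comment, energy_unit = "auto") {
  energy_unit <- match.arg(energy_unit, c("auto", "kcal/mol", "hartree"))
  hit <- .extract_energy(comment)
  if (is.null(hit)) return(NA_real_)
  unit <- energy_unit
  if (!is.na(hit$unit))
    unit <- if (hit$unit %in% c("hartree", "eh", "au")) "hartree"
            else "kcal/mol"
  else if (unit == "auto")
    unit <- if (abs(hit$value) > 100) "hartree" else "kcal/mol"
  if (unit == "hartree") hit$value * confsel_constants$hartree_to_kcal
  else hit$value
}

# label = comment stripped of its energy expression
.comment_label <- function(comment) {
  hit <- .extract_energy(comment)
  if (is.null(hit)) trimws(comment) else hit$rest
}

#' Read a multi-frame XYZ conformer ensemble
#'
#' Parses repeating XYZ blocks (atom-count line, comment line, N coordinate
#' records), one `conformer` per frame in file order. Energies are taken
#' from the comment lines via [parse_comment_energy()]; any remaining
#' comment text becomes the frame label. All frames are checked for an
#' identical element sequence.
#'
#' @param path Path to the XYZ file.
#' @param energy_unit Passed to [parse_comment_energy()].
#' @param name Ensemble name; defaults to the file name.
#' @return A `conformer_ensemble`.
#' @export
read_xyz_ensemble <- function(path, energy_unit = "auto",
                              name = basename(path)) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only; blanks inside a frame are malformed
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) abort_parse(sprintf("empty XYZ file: %s", path))
  structures <- list()
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    nline <- trimws(lines[pos])
    if (!grepl("^[0-9]+$", nline))
      abort_parse(sprintf("frame %d: expected an atom count, got '%s'",
                          frame, nline))
    n <- as.integer(nline)
    if (n < 1L) abort_parse(sprintf("frame %d: atom count must be >= 1", frame))
    if (pos + 1L + n > length(lines))
      abort_parse(sprintf("frame %d: file truncated (need %d atom lines)",
                          frame, n))
    comment <- lines[pos + 1L]
    rec <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- strsplit(trimws(rec), "\\s+")
    if (any(lengths(tok) < 4L))
      abort_parse(sprintf("frame %d: atom record with fewer than 4 fields",
                          frame))
    el <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t) suppressWarnings(as.numeric(t[2:4])),
                    numeric(3)))
    if (anyNA(xyz))
      abort_parse(sprintf("frame %d: non-numeric coordinate", frame))
    structures[[frame]] <- conformer(
      el, xyz,
      energy = parse_comment_energy(comment, energy_unit),
      label  = .comment_label(comment))
    pos <- pos + 2L + n
  }
  conformer_ensemble(structures, name = name)
}

#' Write a conformer ensemble as multi-frame XYZ
#'
#' Round-trip stable with [read_xyz_ensemble()]: elements, labels and
#' energies are reproduced exactly and coordinates to the printed precision
#' (1e-8 Angstrom). Energies are written as `Energy= <value> kcal/mol`
#' followed by the label; frames without an energy carry the label only.
#'
#' @param e A `conformer_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_ensemble <- function(e, path) {
  if (!inherits(e, "conformer_ensemble"))
    abort_contract("e must be a conformer_ensemble")
  con <- tryCatch(file(path, "w"),
                  error = function(err)
                    abort_io(sprintf("cannot write to '%s'", path)))
  on.exit(close(con))
  labs <- ensemble_labels(e)
  for (i in seq_along(e$structures)) {
    s <- e$structures[[i]]
    comment <- if (is.na(s$energy)) labs[i]
               else sprintf("Energy= %.10f kcal/mol %s", s$energy, labs[i])
    writeLines(c(sprintf("%d", length(s$elements)), trimws(comment)), con)
    writeLines(sprintf("%-2s %16.8f %16.8f %16.8f", s$elements,
                       s$coords[, 1], s$coords[, 2], s$coords[, 3]), con)
  }
  invisible(path)
}

#' Attach energies from a sidecar table
#'
#' Two-column text table (whitespace or comma separated): frame index or
#' frame label, then energy in kcal/mol. Frames not mentioned keep their
#' current energy.
#'
#' @param e A `conformer_ensemble`.
#' @param path Path to the table.
#' @return The ensemble with energies filled in.
#' @export
apply_energy_table <- function(e, path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  labs <- ensemble_labels(e)
  for (ln in lines) {
    tok <- strsplit(ln, "[,[:space:]]+")[[1L]]
    if (length(tok) < 2L)
      abort_parse(sprintf("energy table line with fewer than 2 fields: '%s'",
                          ln))
    en <- suppressWarnings(as.numeric(tok[2L]))
    if (is.na(en))
      abort_parse(sprintf("non-numeric energy in table line: '%s'", ln))
    idx <- if (grepl("^[0-9]+$", tok[1L])) as.integer(tok[1L])
           else match(tok[1L], labs)
    if (is.na(idx) || idx < 1L || idx > length(e))
      abort_parse(sprintf("energy table refers to unknown frame '%s'",
                          tok[1L]))
    e$structures[[idx]]$energy <- en
  }
  e
}
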