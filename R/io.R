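# File I/O: FASTA (through Biostrings), Vienna 3-line dot-bracket records,
# TSV reports with provenance headers, and fixture generation. Reports are
# deterministic byte-for-byte for a fixed seed: fixed column order, fixed
# float precision, no timestamps.

#' Read tRNAs from a FASTA file
#'
#' Sequences are normalized (uppercase, T -> U); record ids are preserved
#' verbatim. Sequences of length >= 76 get standard canonical numbering
#' (extra length counted as variable-loop insertions); shorter sequences
#' need `numbering`.
#'
#' @param path FASTA file.
#' @param numbering optional `canonical_numbering` applied to every record.
#' @return list of `trna` objects (empty, with a warning, for an empty
#'   file).
#' @export
read_fasta <- function(path, numbering = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  lapply(seq_along(set), function(i)
    trna(as.character(set[[i]]), id = names(set)[i], numbering = numbering))
}

#' Write tRNAs to a FASTA file
#'
#' 60-column wrapping, ids verbatim.
#'
#' @param trnas a `trna` or list of `trna` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(trnas, path) {
  if (inherits(trnas, "trna")) trnas <- list(trnas)
  set <- Biostrings::BStringSet(vapply(trnas, `[[`, "", "seq"))
  names(set) <- vapply(trnas, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read Vienna records (>id / sequence / dot-bracket)
#' @param path Vienna file.
#' @return list of records, each `list(id, seq, structure)`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0)
    stop("malformed Vienna file (records are 3 lines): ", path)
  lapply(seq(1, length(lines), by = 3), function(i) {
    if (!startsWith(lines[i], ">"))
      stop("expected '>' header at line ", i, " of ", path)
    list(id = sub("^>", "", lines[i]), seq = lines[i + 1],
         structure = lines[i + 2])
  })
}

#' Write Vienna records (unwrapped 3-line format)
#' @param records list of `list(id, seq, structure)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(records, path) {
  out <- unlist(lapply(records, function(r)
    c(paste0(">", r$id), r$seq, r$structure)))
  writeLines(out, path)
  invisible(path)
}

provenance_block <- function(x) {
  c("# trnadesign report",
    paste0("# package_version: ",
           as.character(utils::packageVersion("trnadesign"))),
    if (!is.null(x$config))
      paste0("# config: n_candidates=", x$config$n_candidates,
             " top_k=", x$config$top_k,
             " iterations=", x$config$iterations,
             " seed=", x$config$seed),
    if (!is.null(x$restraints))
      paste0("# restraints: mode=", x$restraints$mode,
             " anticodon=", x$restraints$anticodon),
    if (!is.null(x$model_checksum))
      paste0("# energy_params_md5: ", x$model_checksum))
}

fmt_num <- function(v) {
  ifelse(is.na(v), "NA", formatC(v, digits = 6, format = "g"))
}

#' Write a TSV report
#'
#' Deterministic column order and float rendering (6 significant digits);
#' a leading provenance block (`#` comments) echoes the configuration, the
#' master seed and the energy-parameter checksum. Identical inputs and seed
#' give a byte-identical file.
#'
#' @param x a `design_result`, a `validation_report`, or a list of
#'   validation reports.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "validation_report")) x <- list(x)
  if (inherits(x, "design_result")) {
    df <- x$candidates
    df$p_target <- fmt_num(df$p_target)
    df$mfe_energy <- fmt_num(df$mfe_energy)
    head_lines <- provenance_block(x)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE,
                                      "validation_report"))) {
    df <- data.frame(
      id = vapply(x, `[[`, "", "id"),
      cca_ok = vapply(x, `[[`, TRUE, "cca_ok"),
      g3u70_ok = vapply(x, `[[`, TRUE, "g3u70_ok"),
      identity_ok = vapply(x, `[[`, TRUE, "identity_ok"),
      p_cloverleaf = fmt_num(vapply(x, `[[`, 0, "p_cloverleaf")),
      mfe_energy = fmt_num(vapply(x, `[[`, 0, "mfe_energy")),
      contact_fraction = fmt_num(vapply(x, `[[`, 0, "contact_fraction")),
      pass = vapply(x, `[[`, TRUE, "pass"))
    head_lines <- provenance_block(list())
  } else stop("unsupported report object of class ", class(x)[1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(head_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate fixture files
#'
#' `table1`: writes the combined-restraint template with the cloverleaf
#' target structure as a Vienna record (dots in the sequence line mark
#' unrestrained positions). `random_trnas`: writes `n` random
#' restraint-conforming sequences as FASTA.
#'
#' @param kind `"table1"` or `"random_trnas"`.
#' @param dir output directory (created if missing).
#' @param n number of random sequences.
#' @param seed RNG seed for `random_trnas`.
#' @return paths of the written files.
#' @export
make_fixtures <- function(kind = c("table1", "random_trnas"),
                          dir = ".", n = 10L, seed = 1L) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (kind == "table1") {
    rows <- table1_rows()
    path <- file.path(dir, "design_template.vienna")
    write_vienna(list(list(id = "combined_restraints",
                           seq = rows[["combined"]],
                           structure = rows[["secondary_structure"]])),
                 path)
    return(path)
  }
  set.seed(seed)
  rs <- build_restraints("CUA", "full")
  seqs <- random_conforming(rs, n)
  trnas <- lapply(seq_len(n), function(i)
    trna(seqs[i], id = sprintf("random_conforming_%03d", i)))
  path <- file.path(dir, "random_trnas.fa")
  write_fasta(trnas, path)
  path
}
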