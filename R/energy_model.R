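# Nearest-neighbor energy model: loader for the sectioned parameter TSV and
# helpers shared by the folding routines.

PAIR_TYPES <- c("AU", "CG", "GC", "GU", "UA", "UG")

#' Load a nearest-neighbor energy model
#'
#' Reads a sectioned TSV parameter file (`[general]`, `[stacks]`,
#' `[hairpin]`, `[internal]`, `[bulge]`, `[multiloop]`; units kcal/mol) and
#' attaches the temperature-derived `RT`. The packaged default model is a
#' compact Turner-style set: stacking energies for the six allowed pairs
#' (AU, UA, CG, GC, GU, UG), size-dependent hairpin/internal/bulge
#' penalties with logarithmic extrapolation beyond the tabulated sizes,
#' Ninio-style internal-loop asymmetry, and an affine multiloop cost.
#' Minimum hairpin loop is 3; lonely pairs are permitted.
#'
#' @param path parameter file; default: the packaged table.
#' @param temperature kelvin (default 310.15, i.e. 37 C).
#' @return an `energy_model` object.
#' @export
energy_model <- function(path = NULL, temperature = 310.15) {
  if (is.null(path))
    path <- system.file("extdata", "energy_params.tsv",
                        package = "trnadesign", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  section <- NA_character_
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  hairpin <- internal <- bulge <- numeric(0)
  gen <- ml <- list()
  asym <- asym_max <- NA_real_
  for (ln in lines) {
    if (grepl("^\\[", ln)) { section <- gsub("\\[|\\]", "", ln); next }
    f <- strsplit(ln, "\t")[[1]]
    if (section == "general") gen[[f[1]]] <- as.numeric(f[2])
    else if (section == "stacks") stack[f[1], f[2]] <- as.numeric(f[3])
    else if (section == "hairpin") hairpin[f[1]] <- as.numeric(f[2])
    else if (section == "internal") {
      if (f[1] == "asym") asym <- as.numeric(f[2])
      else if (f[1] == "asym_max") asym_max <- as.numeric(f[2])
      else internal[f[1]] <- as.numeric(f[2])
    }
    else if (section == "bulge") bulge[f[1]] <- as.numeric(f[2])
    else if (section == "multiloop") ml[[f[1]]] <- as.numeric(f[2])
  }
  if (anyNA(stack)) stop("incomplete stack table in ", path)
  ord <- function(v) v[as.character(sort(as.integer(names(v))))]
  model <- structure(list(
    stack = stack,
    hairpin = ord(hairpin), internal = ord(internal), bulge = ord(bulge),
    asym = asym, asym_max = asym_max,
    ml_closing = ml$closing, ml_branch = ml$branch,
    ml_unpaired = ml$unpaired,
    lxc = gen$lxc, maxloop = as.integer(gen$maxloop),
    temperature = temperature,
    RT = 1.98717e-3 * temperature,
    path = path,
    checksum = unname(tools::md5sum(path))),
    class = "energy_model")
  model
}

#' @export
print.energy_model <- function(x, ...) {
  cat("energy_model: T =", x$temperature, "K (RT =",
      format(x$RT, digits = 5), "kcal/mol),",
      "params", basename(x$path), "\n")
  invisible(x)
}

#' Packaged default energy model at 37 C
#' @return an `energy_model` (memoized).
#' @export
default_energy_model <- function() {
  if (is.null(.trnadesign_env$model))
    .trnadesign_env$model <- energy_model()
  .trnadesign_env$model
}

# parameter list handed to the compiled routines
cpar <- function(model) {
  list(stack = unname(model$stack),
       hairpin = unname(model$hairpin),
       internal = unname(model$internal),
       bulge = unname(model$bulge),
       asym = model$asym, asym_max = model$asym_max,
       ml_closing = model$ml_closing, ml_branch = model$ml_branch,
       ml_unpaired = model$ml_unpaired,
       lxc = model$lxc, maxloop = model$maxloop)
}

seq_codes <- function(seq) {
  m <- match(strsplit(seq, "")[[1]], RNA_BASES)
  if (anyNA(m)) stop("sequence contains non-ACGU characters")
  as.integer(m - 1L)
}

#' Is a base combination an allowed pair?
#' @param b1,b2 single bases (5' and 3' partner).
#' @return logical.
#' @export
is_allowed_pair <- function(b1, b2) {
  paste0(b1, b2) %in% PAIR_TYPES
}
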