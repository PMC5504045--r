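# Extended-XYZ dialect for conformations and trajectories.
# Per frame: line 1 = N; line 2 = comment with key=value metadata
# (temperature, energy, step, replica); then N atom lines with fixed
# column order: x y z qw qx qy qz type.

frame_comment <- function(meta) {
  if (length(meta) == 0) return("frame")
  paste(sprintf("%s=%s", names(meta),
                vapply(meta, function(v) format(v, digits = 12), "")),
        collapse = " ")
}

#' Write chain states to an extended-XYZ trajectory file
#'
#' @param states A [chain_state()] or a list of them.
#' @param path Output file.
#' @param metadata Optional list (one element per frame) of named lists
#'   written into the comment line (e.g. `temperature`, `energy`,
#'   `step`, `replica`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(states, path, metadata = NULL) {
  if (inherits(states, "chain_state")) states <- list(states)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(states)) {
    st <- states[[k]]
    n <- n_beads(st)
    writeLines(as.character(n), con)
    writeLines(frame_comment(if (is.null(metadata)) list()
                             else metadata[[k]]), con)
    rows <- sprintf("%.12g %.12g %.12g %.12g %.12g %.12g %.12g %d",
                    st$positions[, 1], st$positions[, 2],
                    st$positions[, 3], st$orientations[, 1],
                    st$orientations[, 2], st$orientations[, 3],
                    st$orientations[, 4], st$sequence - 1L)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by [write_xyz()]
#'
#' @param path Input file.
#' @return A list of [chain_state()] objects; each carries a `meta`
#'   attribute with the parsed comment-line key=value pairs.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    block <- lines[(i + 2):(i + 1 + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    st <- chain_state(m[, 1:3, drop = FALSE], m[, 4:7, drop = FALSE],
                      as.integer(m[, 8]) + 1L)
    kv <- regmatches(comment, gregexpr("[A-Za-z_]+=[^ ]+", comment))[[1]]
    meta <- list()
    for (p in kv) {
      parts <- strsplit(p, "=")[[1]]
      val <- suppressWarnings(as.numeric(parts[2]))
      meta[[parts[1]]] <- if (is.na(val)) parts[2] else val
    }
    attr(st, "meta") <- meta
    out[[length(out) + 1]] <- st
    i <- i + 2 + n
  }
  out
}

#' Write / read an interaction matrix as a plain-text symmetric table
#'
#' @param imat A [sample_interaction_matrix()] object.
#' @param path File path.
#' @return `path` (writer) or an `interaction_matrix` (reader).
#' @export
write_interaction_matrix <- function(imat, path) {
  writeLines(c(sprintf("# q %d", imat$q),
               sprintf("# seed %s",
                       if (is.null(imat$seed)) "NA" else imat$seed)), path)
  suppressWarnings(
    write.table(format(imat$eps, digits = 17), path, append = TRUE,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE))
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  q <- as.integer(sub("# q ", "", hdr[grepl("^# q ", hdr)]))
  seed_s <- sub("# seed ", "", hdr[grepl("^# seed ", hdr)])
  seed <- if (seed_s == "NA") NULL else as.integer(seed_s)
  eps <- as.matrix(read.table(text = lines[!startsWith(lines, "#")]))
  dimnames(eps) <- NULL
  stopifnot(nrow(eps) == q, ncol(eps) == q)
  structure(list(q = q, eps = eps, seed = seed, sd = stats::sd(
    eps[upper.tri(eps, diag = TRUE)])), class = "interaction_matrix")
}

#' Write / read a designed sequence as plain text
#'
#' One type label per line (integers `1..q`), after a header recording
#' the chain length and alphabet size.
#'
#' @param sequence Integer sequence (or `designed_sequence`).
#' @param q Alphabet size for the header.
#' @param path File path.
#' @return `path` (writer) or an integer vector with attribute `q`
#'   (reader).
#' @export
write_sequence <- function(sequence, path, q = max(sequence)) {
  if (inherits(sequence, "designed_sequence")) sequence <- sequence$sequence
  writeLines(c(sprintf("# n %d q %d", length(sequence), q),
               as.character(sequence)), path)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  q <- as.integer(sub(".*q ", "", hdr))
  s <- as.integer(lines[!startsWith(lines, "#")])
  attr(s, "q") <- q
  s
}

#' Write / read a free-energy profile as TSV
#'
#' Columns: `bin_left`, `bin_right`, `F`, `err`, `temperature`.
#'
#' @param profile A [free_energy_profile()].
#' @param path File path.
#' @return `path` (writer) or a `free_energy_profile` (reader).
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(bin_left = profile$bin_left,
                   bin_right = profile$bin_right,
                   F = profile$F, err = profile$err,
                   temperature = attr(profile, "temperature"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  bw <- stats::median(df$bin_right - df$bin_left)
  out <- tibble(bin_left = df$bin_left, bin_right = df$bin_right,
                bin_mid = (df$bin_left + df$bin_right) / 2,
                count = NA_real_, F = df$F, err = df$err)
  structure(out, class = c("free_energy_profile", class(out)),
            temperature = df$temperature[1], bin_width = bw)
}

#' Write a radial distribution function as TSV
#'
#' The header records the exclusion rule, bin width and normalisation.
#'
#' @param gr A [radial_distribution()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gr <- function(gr, path) {
  writeLines(c(sprintf("# bin_width %g", attr(gr, "bin_width")),
               sprintf("# exclude_neighbours %s", attr(gr, "exclude")),
               sprintf("# ball_radius %g", attr(gr, "ball_radius")),
               sprintf("# n_conformations %s",
                       attr(gr, "n_conformations"))), path)
  suppressWarnings(
    write.table(as.data.frame(gr), path, append = TRUE, sep = "\t",
                quote = FALSE, row.names = FALSE))
  invisible(path)
}

config_keys <- c("n", "q", "n_patches", "chain_model", "seed",
                 "matrix_seed", "n_runs", "sweeps", "burnin", "stride",
                 "bin_width", "seek_energy_bin", "heterogeneity",
                 "convergence_tol", "strict_convergence",
                 "temperature_ladder", "allow_extended_alphabet")

#' Load / save a run configuration (JSON)
#'
#' A flat JSON object whose keys are the arguments of [run_config()];
#' unknown keys are rejected by name, missing keys take the standard
#' defaults, and an empty file yields the full default configuration
#' (50-mer, 16-temperature ladder).
#'
#' @param path File path.
#' @param config A [run_config()] (saver).
#' @return A `run_config` (loader) or `path` (saver).
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  bad <- setdiff(names(vals), config_keys)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  vals <- config[intersect(config_keys, names(config))]
  vals$temperature_ladder <- config$params$temperature_ladder
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
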