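#' @title File formats and run manifests
#'
#' @description Designed sequences are exported as FASTA (with run/sample
#' indices and oracle scores in the headers), optimized position probability
#' matrices as MEME minimal motif format, and per-update loss trajectories as
#' JSON lines. Oracle fixtures are described by small YAML specs, and every
#' CLI run writes a JSON manifest sufficient to reproduce it.
#'
#' @name io-formats
NULL

#' Write designed sequences to FASTA
#'
#' Headers follow `run<k>_sample<s> score=<P(x) to 6 decimals>`; the argmax
#' sequence of a run uses sample index 0.
#'
#' @param sequences a list of one-hot matrices, or a character vector.
#' @param alph an [alphabet()].
#' @param path output file.
#' @param scores numeric vector of oracle scores (optional).
#' @param names_ character vector of record names; default
#'   `run0_sample1, ...`.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, alph, path, scores = NULL, names_ = NULL) {
  if (is.character(sequences)) {
    strs <- sequences
  } else {
    if (is.matrix(sequences)) sequences <- list(sequences)
    strs <- vapply(sequences, onehot_to_string, character(1), alph = alph)
  }
  if (is.null(names_))
    names_ <- sprintf("run0_sample%d", seq_along(strs))
  if (!is.null(scores))
    names_ <- sprintf("%s score=%.6f", names_, scores)
  set <- switch(attr(alph, "mode") %||% "custom",
    dna = Biostrings::DNAStringSet(strs),
    protein = Biostrings::AAStringSet(strs),
    Biostrings::BStringSet(strs)
  )
  names(set) <- names_
  tryCatch(
    Biostrings::writeXStringSet(set, filepath = path),
    error = function(e) stop("failed to write FASTA to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a FASTA file of designs back as one-hot matrices
#'
#' @param path FASTA file.
#' @param alph the [alphabet()] the file was written with.
#' @return A named list of one-hot matrices.
#' @export
read_fasta_onehot <- function(path, alph) {
  set <- switch(attr(alph, "mode") %||% "custom",
    dna = Biostrings::readDNAStringSet(path),
    protein = Biostrings::readAAStringSet(path),
    Biostrings::readBStringSet(path)
  )
  out <- lapply(as.character(set), string_to_onehot, alph = alph)
  names(out) <- names(set)
  out
}

#' Write a PSSM in MEME minimal motif format
#'
#' Emits a version line, the ALPHABET, and a letter-probability matrix with
#' `w = N`. Probabilities are printed to 6 decimals and each row is
#' renormalized after rounding so printed rows sum to exactly 1.000000.
#'
#' @param pssm an N x M row-stochastic matrix.
#' @param alph an [alphabet()].
#' @param path output file.
#' @param name motif name (default `"design"`).
#' @return The path, invisibly.
#' @export
write_pssm_meme <- function(pssm, alph, path, name = "design") {
  check_finite_matrix(pssm, "PSSM")
  if (any(pssm < 0) || any(abs(rowSums(pssm) - 1) > 1e-6))
    stop("PSSM rows must be non-negative and sum to 1")
  rows <- apply(pssm, 1, function(r) {
    r6 <- round(r, 6)
    # push the rounding residue onto the largest entry so the printed row
    # sums to exactly 1
    r6[which.max(r6)] <- r6[which.max(r6)] + (1 - sum(r6))
    paste(sprintf("%.6f", r6), collapse = " ")
  })
  lines <- c(
    "MEME version 4",
    "",
    sprintf("ALPHABET= %s", paste(unclass(alph), collapse = "")),
    "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= %d w= %d nsites= 1 E= 0",
            ncol(pssm), nrow(pssm)),
    rows,
    ""
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' Minimal reader for the subset written by [write_pssm_meme()] (one motif,
#' letter-probability matrix).
#'
#' @param path MEME file.
#' @return A list with `pssm`, `alphabet` (character vector) and `name`.
#' @export
read_pssm_meme <- function(path) {
  lines <- readLines(path)
  al_line <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(al_line) != 1) stop("not a minimal MEME motif file: ", path)
  symbols <- strsplit(sub("^ALPHABET=\\s*", "", al_line), "")[[1]]
  mot <- grep("^MOTIF ", lines)
  hdr <- grep("^letter-probability matrix:", lines)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr[1]]))
  mat_lines <- lines[(hdr[1] + 1):(hdr[1] + w)]
  pssm <- do.call(rbind, lapply(strsplit(trimws(mat_lines), "\\s+"), as.numeric))
  list(pssm = pssm, alphabet = symbols,
       name = sub("^MOTIF\\s+", "", lines[mot[1]]))
}

#' Write a loss trajectory as JSON lines
#'
#' One JSON object per logged update: `{"step": ..., "train_loss": ...,
#' "test_loss": ..., "gamma_summary": ...}` (test_loss/gamma fields omitted
#' where not logged). Step indices are strictly increasing within a run.
#'
#' @param trajectory the `trajectory` tibble of an `fsp_design_result`
#'   (single run or with a `run` column).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trajectory_jsonl <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  has_run <- "run" %in% names(trajectory)
  has_gamma <- "gamma_mean" %in% names(trajectory)
  lines <- vapply(seq_len(nrow(trajectory)), function(i) {
    obj <- list()
    if (has_run) obj$run <- trajectory$run[i]
    obj$step <- trajectory$step[i]
    obj$train_loss <- trajectory$train_loss[i]
    if (!is.na(trajectory$test_loss[i])) obj$test_loss <- trajectory$test_loss[i]
    if (has_gamma) obj$gamma_summary <- trajectory$gamma_mean[i]
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a JSONL trajectory
#'
#' @param path JSONL file.
#' @return A tibble with one row per line.
#' @export
read_trajectory_jsonl <- function(path) {
  rows <- lapply(readLines(path), function(ln) {
    as.data.frame(jsonlite::fromJSON(ln))
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Build an oracle from a YAML spec
#'
#' Supported kinds: `linear` (fields: `W`, a list of rows, or `n_pos` +
#' `seed` to draw a standard-normal W), `motif` (fields: `kmer_weights` rows
#' or `k` + `seed`, `n_pos`, optional `sharpness`), `hamming` (fields:
#' `target` string, `alphabet`), `toy_structure` (fields: `n_pos`, `seed`,
#' optional `embed_dim`, `sharpness`).
#'
#' @param spec a file path to a YAML document, or an already-parsed list.
#' @param alph an [alphabet()] (overridden by an `alphabet` field in the
#'   spec).
#' @return An `fsp_oracle`.
#' @export
oracle_from_spec <- function(spec, alph = alphabet("dna")) {
  if (is.character(spec)) {
    if (!file.exists(spec)) stop("oracle spec not found: ", spec)
    spec <- yaml::read_yaml(spec)
  }
  if (!is.null(spec$alphabet)) alph <- alphabet(spec$alphabet)
  m <- length(alph)
  kind <- spec$kind %||% stop("oracle spec needs a 'kind'")
  as_mat <- function(x) do.call(rbind, lapply(x, as.numeric))
  switch(kind,
    linear = {
      W <- if (!is.null(spec$W)) as_mat(spec$W) else {
        old <- .Random.seed_exists()
        set.seed(spec$seed %||% 1)
        W <- matrix(stats::rnorm(spec$n_pos * m), spec$n_pos, m)
        .Random.seed_restore(old)
        W
      }
      make_linear_oracle(W)
    },
    motif = {
      kw <- if (!is.null(spec$kmer_weights)) as_mat(spec$kmer_weights) else {
        old <- .Random.seed_exists()
        set.seed(spec$seed %||% 1)
        kw <- matrix(stats::rnorm(spec$k * m), spec$k, m)
        .Random.seed_restore(old)
        kw
      }
      make_motif_oracle(kw, n_pos = spec$n_pos,
                        sharpness = spec$sharpness %||% 10)
    },
    hamming = make_hamming_oracle(string_to_onehot(spec$target, alph)),
    toy_structure = {
      make_toy_structure_predictor(
        n_pos = spec$n_pos %||% 20,
        alph = if (attr(alph, "mode") == "dna" && is.null(spec$alphabet))
                 alphabet("protein") else alph,
        embed_dim = spec$embed_dim %||% 6,
        sharpness = spec$sharpness %||% 2,
        seed = spec$seed %||% 1
      )$oracle
    },
    stop("unknown oracle kind: ", kind)
  )
}

#' Write an oracle spec to YAML
#'
#' @param spec a list as accepted by [oracle_from_spec()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_oracle_spec <- function(spec, path) {
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Write structure target tensors as JSON
#'
#' Stores the four named probability tensors (`distance`, `theta`, `omega`,
#' `phi`) with their dimensions in a plain-text JSON archive.
#'
#' @param target a named list of N x N x bins arrays.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_structure_target <- function(target, path) {
  obj <- lapply(target, function(a) list(dim = dim(a), data = as.numeric(a)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read structure target tensors from JSON
#'
#' @param path file written by [write_structure_target()].
#' @return A named list of arrays.
#' @export
read_structure_target <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(obj, function(o) array(o$data, dim = o$dim))
}

#' Write a run manifest
#'
#' A JSON snapshot of the configuration, seed, method, oracle spec, package
#' version and output paths — sufficient to reproduce the run bit-for-bit.
#'
#' @param config an [design_config()] (or any list).
#' @param oracle_spec the oracle spec list (or path).
#' @param outputs named list/character of output paths.
#' @param path manifest file.
#' @return The path, invisibly.
#' @export
write_manifest <- function(config, oracle_spec, outputs, path) {
  cfg <- unclass(config)
  cfg$alph <- list(mode = attr(config$alph, "mode"),
                   symbols = paste(unclass(config$alph), collapse = ""))
  cfg$est <- unclass(cfg$est)
  man <- list(
    package = "fastseqprop",
    version = as.character(utils::packageVersion("fastseqprop")),
    config = cfg,
    oracle = oracle_spec,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
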