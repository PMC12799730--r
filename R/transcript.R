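#' Generate a random codon-class sequence
#'
#' Produces a transcript of `L` codon classes (1 = optimal, 2 = non-optimal)
#' with a requested fraction of optimal codons. In `"exact"` mode exactly
#' `round(f_op * L)` optimal codons are placed at uniformly random positions;
#' in `"bernoulli"` mode each position is optimal independently with
#' probability `f_op` (so the realized fraction fluctuates around `f_op`).
#' Given the same `seed`, the sequence is reproducible; the caller's RNG
#' state is left untouched.
#'
#' @param L Transcript length in codons.
#' @param f_op Requested fraction of optimal codons, in `[0, 1]`.
#' @param seed Integer seed; `NULL` uses (and advances) the session RNG.
#' @param mode `"exact"` (exact count, random placement) or `"bernoulli"`.
#' @return An integer vector of class `codon_transcript` (values 1/2) with
#'   attributes `f_op_requested` and `f_op_realized`.
#' @examples
#' tr <- generate_transcript(300, 0.7, seed = 1)
#' attr(tr, "f_op_realized")
#' @export
generate_transcript <- function(L, f_op, seed = NULL,
                                mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  if (!is.numeric(L) || L < 1) stop("L must be >= 1", call. = FALSE)
  if (!is.numeric(f_op) || f_op < 0 || f_op > 1) {
    stop("f_op must lie in [0, 1]", call. = FALSE)
  }
  L <- as.integer(L)
  draw <- function() {
    if (mode == "exact") {
      k <- round(f_op * L)
      s <- rep(2L, L)
      if (k > 0) s[sample.int(L, k)] <- 1L
      s
    } else {
      ifelse(stats::runif(L) < f_op, 1L, 2L)
    }
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  s <- draw()
  structure(s, class = "codon_transcript",
            f_op_requested = f_op, f_op_realized = mean(s == 1L))
}

#' @export
print.codon_transcript <- function(x, ...) {
  cat(sprintf("codon transcript: %d codons, f_op realized %.4g (requested %g)\n",
              length(x), attr(x, "f_op_realized"), attr(x, "f_op_requested")))
  chars <- paste(ifelse(unclass(x) == 1L, "O", "N"), collapse = "")
  if (nchar(chars) > 60) chars <- paste0(substr(chars, 1, 60), "...")
  cat(" ", chars, "\n")
  invisible(x)
}

#' Write / read codon-class sequences as plain text
#'
#' One-character-per-codon strings (`O` = optimal, `N` = non-optimal), one
#' transcript per record, each preceded by a header line
#' `"> transcript <i> L=<L> f_op=<realized>"`. This is deliberately not
#' FASTA: the symbols are codon classes, not nucleotides.
#'
#' @param transcripts A `codon_transcript` or list of them.
#' @param path File path.
#' @return `write_transcripts()` returns `path` invisibly;
#'   `read_transcripts()` returns a list of `codon_transcript` objects.
#' @export
write_transcripts <- function(transcripts, path) {
  if (inherits(transcripts, "codon_transcript")) {
    transcripts <- list(transcripts)
  }
  lines <- unlist(purrr::imap(transcripts, function(tr, i) {
    c(sprintf("> transcript %d L=%d f_op=%.10g", i, length(tr),
              attr(tr, "f_op_realized")),
      paste(ifelse(unclass(tr) == 1L, "O", "N"), collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no transcript records in ", path, call. = FALSE)
  purrr::map(heads, function(h) {
    body <- lines[h + 1]
    s <- ifelse(strsplit(body, "")[[1]] == "O", 1L, 2L)
    structure(s, class = "codon_transcript",
              f_op_requested = mean(s == 1L), f_op_realized = mean(s == 1L))
  })
}
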