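#' Evolve sequences along a locus genealogy under JC69
#'
#' Draws the root state of each site uniformly from \{T, C, A, G\} and
#' evolves it down the segment tree containing the site: along a branch of
#' length `t` (expected substitutions per site) a site keeps its state with
#' probability `1/4 + 3/4 exp(-4t/3)` and changes to each other state with
#' probability `1/4 - 1/4 exp(-4t/3)`.  Sites within a segment are i.i.d.
#' given that segment's tree; segments are concatenated in breakpoint order.
#'
#' @param g a `locus_genealogy` simulated with `trees = TRUE`.
#' @param seed optional integer seed for the mutation process.
#' @return a `locus_alignment`: a character matrix (sequences x sites) over
#'   \{T, C, A, G\} with the sample labels as row names.
#' @export
evolve_jc <- function(g, seed = NULL) {
  stopifnot(inherits(g, "locus_genealogy"))
  if (is.null(g$records)) stop("genealogy was simulated without trees")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rec <- g$records
  mat <- .evolve_jc_cpp(length(g$labels), g$n, rec$age, rec$child1,
                        rec$child2, rec$start, rec$end, g$breakpoints)
  aln <- matrix(c("T", "C", "A", "G")[mat + 1L], nrow = nrow(mat))
  rownames(aln) <- g$labels
  class(aln) <- c("locus_alignment", class(aln))
  aln
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus_alignment: %d sequences x %d sites\n",
              nrow(x), ncol(x)))
  invisible(x)
}

as_alignment <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicate sequence labels")
  if (!all(mat %in% c("T", "C", "A", "G")))
    stop("alignment states must be T, C, A or G")
  class(mat) <- c("locus_alignment", "matrix", "array")
  mat
}

#' Simulate a replicate's multilocus alignments
#'
#' Runs the ancestral-recombination-graph simulator and JC69 evolution for
#' every locus of one replicate, using the design's per-locus seed scheme
#' (`seed + replicate * L + locus`), so replicates and loci are reproducible
#' independently.
#'
#' @param net a `species_network`.
#' @param map a sample map.
#' @param design a [sim_design()].
#' @param replicate 0-based replicate index.
#' @return a list of `L` `locus_alignment` objects, with the per-locus
#'   genealogies attached as attribute `"genealogies"`.
#' @export
simulate_alignments <- function(net, map, design, replicate = 0L) {
  alns <- vector("list", design$L)
  gl <- vector("list", design$L)
  for (locus in 0:(design$L - 1L)) {
    set.seed(design$seed + replicate * design$L + locus)
    g <- simulate_locus(net, map, design, trees = TRUE)
    gl[[locus + 1L]] <- g
    alns[[locus + 1L]] <- evolve_jc(g)
  }
  attr(alns, "genealogies") <- gl
  alns
}

#' Alignment I/O (sequential PHYLIP and FASTA)
#'
#' `write_alignment()` writes one locus; with `append = TRUE` successive loci
#' are concatenated into a multilocus file (the PHYLIP form is the
#' bpp-style multilocus stack of sequential-PHYLIP blocks).
#' `read_alignment()` reads all loci back and returns a list of alignments;
#' reading then writing reproduces the matrices exactly.
#'
#' @param a a `locus_alignment` (character matrix with row names).
#' @param file path.
#' @param format `"phylip"` or `"fasta"`.
#' @param append append to an existing multilocus file.
#' @return `file`, invisibly.
#' @export
write_alignment <- function(a, file, format = c("phylip", "fasta"),
                            append = FALSE) {
  format <- match.arg(format)
  if (anyDuplicated(rownames(a))) stop("duplicate sequence labels")
  seqs <- apply(a, 1L, paste, collapse = "")
  if (format == "phylip") {
    lines <- c(paste(nrow(a), ncol(a)),
               paste0(format(rownames(a), width = max(nchar(rownames(a)))),
                      "  ", seqs), "")
  } else {
    lines <- as.vector(rbind(paste0(">", rownames(a)), seqs))
  }
  con <- file(file, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(file, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  lines <- readLines(file)
  out <- list()
  if (format == "phylip") {
    i <- 1L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      hd <- as.integer(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]])
      if (length(hd) != 2L || anyNA(hd)) stop("malformed PHYLIP header")
      ns <- hd[1]
      block <- lines[(i + 1L):(i + ns)]
      parts <- regmatches(block,
                          regexec("^(\\S+)\\s+(\\S+)\\s*$", block))
      labs <- vapply(parts, `[`, "", 2L)
      seqs <- vapply(parts, `[`, "", 3L)
      if (any(nchar(seqs) != hd[2])) stop("sequence length != header")
      mat <- t(vapply(strsplit(seqs, ""), identity, character(hd[2])))
      rownames(mat) <- labs
      out[[length(out) + 1L]] <- as_alignment(mat)
      i <- i + 1L + ns
    }
  } else {
    starts <- grep("^>", lines)
    if (!length(starts)) stop("no FASTA records")
    labs <- sub("^>", "", lines[starts])
    ends <- c(starts[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(starts), function(k)
      paste(lines[(starts[k] + 1L):ends[k]], collapse = ""), "")
    mat <- t(vapply(strsplit(seqs, ""), identity, character(nchar(seqs[1]))))
    rownames(mat) <- labs
    # FASTA holds one locus per file in this package
    out[[1L]] <- as_alignment(mat)
  }
  if (length(out) == 1L) out[[1L]] else out
}
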