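## Extended-Newick I/O for species networks.
##
## Format: standard Newick, plus
##   * every node may carry an attribute comment  [&age=<x>,theta=<x>,phi=<x>]
##   * a hybridization node appears twice, linked by a  #H<k>  tag: once as an
##     internal node holding its child (under its main parent), once as a
##     pseudo-leaf under its second parent.  The `phi` attribute sits on the
##     edge it annotates (pseudo-leaf occurrence: probability of the second
##     parent edge; primary occurrence: probability of the main edge).
## Ages may alternatively be supplied through ultrametric branch lengths.

#' Serialize a species network to extended Newick
#'
#' @param net a `species_network`.
#' @param file optional path; when given the string is written to it.
#' @return the extended-Newick string, invisibly when `file` is given.
#' @export
write_species_network <- function(net, file = NULL) {
  validate_species_network(net)
  nd <- net$nodes
  n <- nrow(nd)
  hyb <- which(!is.na(nd$parent2))
  tag <- rep(NA_character_, n)
  if (length(hyb)) tag[hyb] <- paste0("#H", seq_along(hyb))
  num <- function(x) {
    s <- sprintf("%.15g", x)          # shortest exact form where possible
    bad <- as.numeric(s) != x
    s[bad] <- sprintf("%.17g", x[bad])
    s
  }
  attrs <- function(i) {
    paste0("[&age=", num(nd$age[i]), ",theta=", num(nd$theta[i]), "]")
  }
  kids_of <- lapply(seq_len(n), function(i)
    which(!is.na(nd$parent) & nd$parent == i))
  # pseudo-leaves attached under the second parent
  pseudo <- lapply(seq_len(n), function(i) hyb[nd$parent2[hyb] == i])
  rec <- function(i) {
    kids <- kids_of[[i]]
    parts <- character(0)
    if (length(kids)) parts <- vapply(kids, rec, "")
    if (length(pseudo[[i]]))
      parts <- c(parts, vapply(pseudo[[i]], function(h)
        paste0(nd$label[h], tag[h], "[&phi=", num(nd$phi[h]), "]"), ""))
    lab <- paste0(nd$label[i], if (!is.na(tag[i])) tag[i] else "", attrs(i))
    if (length(parts))
      paste0("(", paste(sort(parts), collapse = ","), ")", lab)
    else lab
  }
  root <- which(is.na(nd$parent))
  out <- paste0(rec(root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Parse an extended-Newick species network
#'
#' Accepts plain Newick species trees (with `age`/`theta` attribute comments,
#' or ultrametric branch lengths from which ages are derived) and extended
#' Newick with `#H` hybridization tags.
#'
#' @param text a single extended-Newick string (or a path would first be read
#'   by the caller; this function takes text).
#' @return a validated `species_network`; `parse(write(net))` reproduces
#'   `net` up to node order.
#' @export
parse_species_network <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("syntax error: empty string")
  env <- new.env()
  env$pos <- 1L
  env$s <- s
  nrec <- list()   # per occurrence: label, tag, age, theta, phi, brlen, parent
  add <- function(rec) {
    nrec[[length(nrec) + 1L]] <<- rec
    length(nrec)
  }
  peek <- function() {
    if (env$pos > nchar(env$s)) "" else substr(env$s, env$pos, env$pos)
  }
  advance <- function(k = 1L) env$pos <- env$pos + k
  parse_label_part <- function() {
    rest <- substr(env$s, env$pos, nchar(env$s))
    m <- regmatches(rest, regexec(
      "^([^():,;#[]*)(#[A-Za-z0-9_]+)?(\\[&[^]]*\\])?(:[0-9eE.+-]+)?",
      rest))[[1]]
    advance(nchar(m[1]))
    att <- list(age = NA_real_, theta = NA_real_, phi = NA_real_)
    if (nzchar(m[4])) {
      body <- sub("^\\[&", "", sub("\\]$", "", m[4]))
      for (kv in strsplit(body, ",", fixed = TRUE)[[1]]) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        if (length(p) != 2L || !p[1] %in% c("age", "theta", "phi"))
          stop("syntax error: bad attribute '", kv, "'")
        att[[p[1]]] <- as.numeric(p[2])
      }
    }
    list(label = m[2],
         tag = if (nzchar(m[3])) m[3] else NA_character_,
         age = att$age, theta = att$theta, phi = att$phi,
         brlen = if (nzchar(m[5])) as.numeric(substring(m[5], 2)) else NA_real_)
  }
  parse_clade <- function(parent) {
    kids_present <- FALSE
    self <- NA_integer_
    if (peek() == "(") {
      advance()
      kids_present <- TRUE
      lab <- NULL
      kid_ids <- integer(0)
      repeat {
        kid_ids <- c(kid_ids, parse_clade(NA_integer_))
        ch <- peek()
        if (ch == ",") { advance(); next }
        if (ch == ")") { advance(); break }
        stop("syntax error: unbalanced parentheses")
      }
      rec <- parse_label_part()
      rec$parent <- parent
      self <- add(rec)
      for (k in kid_ids) nrec[[k]]$parent <<- self
    } else {
      rec <- parse_label_part()
      if (!nzchar(rec$label) && is.na(rec$tag))
        stop("syntax error: empty node at position ", env$pos)
      rec$parent <- parent
      self <- add(rec)
    }
    self
  }
  root_id <- parse_clade(NA_integer_)
  if (peek() != ";") stop("syntax error: expected ';' at position ", env$pos)
  advance()
  if (env$pos <= nchar(s)) stop("syntax error: trailing characters")

  occ <- nrec
  no <- length(occ)
  kid_count <- integer(no)
  for (i in seq_len(no))
    if (!is.na(occ[[i]]$parent))
      kid_count[occ[[i]]$parent] <- kid_count[occ[[i]]$parent] + 1L

  tags <- vapply(occ, function(r) r$tag, "")
  tagged <- split(seq_len(no), tags)
  tagged <- tagged[!is.na(names(tagged)) & names(tagged) != "NA"]
  primary_of <- stats::setNames(rep(NA_integer_, length(tagged)), names(tagged))
  drop <- integer(0)
  hyb_parent2 <- list()
  for (tg in names(tagged)) {
    ids <- tagged[[tg]]
    if (length(ids) != 2L)
      stop("hybrid node ", tg, " must have exactly 2 parents (",
           length(ids), " occurrence(s) found)")
    withkids <- ids[kid_count[ids] > 0L]
    leaves <- ids[kid_count[ids] == 0L]
    if (length(withkids) != 1L)
      stop("hybrid node ", tg,
           " must have exactly one child-bearing occurrence")
    pri <- withkids; lf <- leaves
    phi2 <- occ[[lf]]$phi
    phi1 <- occ[[pri]]$phi
    if (!is.na(phi1) && !is.na(phi2) && abs(phi1 + phi2 - 1) > 1e-9)
      stop("inheritance probabilities of hybrid ", tg, " must sum to 1")
    if (is.na(phi2)) phi2 <- if (!is.na(phi1)) 1 - phi1 else
      stop("hybrid node ", tg, " carries no inheritance probability")
    if (phi2 < 0 || phi2 > 1) stop("phi must lie in [0, 1]")
    primary_of[tg] <- pri
    hyb_parent2[[tg]] <- occ[[lf]]$parent
    occ[[pri]]$phi <- phi2
    if (!is.na(occ[[lf]]$age) && !is.na(occ[[pri]]$age) &&
        occ[[lf]]$age != occ[[pri]]$age)
      stop("the two occurrences of hybrid ", tg, " disagree on age")
    drop <- c(drop, lf)
  }
  keep <- setdiff(seq_len(no), drop)
  newid <- rep(NA_integer_, no); newid[keep] <- seq_along(keep)

  label <- vapply(keep, function(i) occ[[i]]$label, "")
  age <- vapply(keep, function(i) occ[[i]]$age, 0)
  theta <- vapply(keep, function(i) occ[[i]]$theta, 0)
  phiv <- rep(NA_real_, length(keep))
  parent <- vapply(keep, function(i) {
    p <- occ[[i]]$parent
    if (is.na(p)) NA_integer_ else newid[p]
  }, 1L)
  parent2 <- rep(NA_integer_, length(keep))
  for (tg in names(tagged)) {
    i <- newid[primary_of[tg]]
    parent2[i] <- newid[hyb_parent2[[tg]]]
    phiv[i] <- occ[[primary_of[tg]]]$phi
  }
  brlen <- vapply(keep, function(i) occ[[i]]$brlen, 0)

  if (all(is.na(age))) {
    # derive ages from ultrametric branch lengths
    if (all(is.na(brlen))) stop("no ages and no branch lengths given")
    depth <- rep(NA_real_, length(keep))
    rt <- which(is.na(parent))
    depth_of <- function(i) {
      if (!is.na(depth[i])) return(depth[i])
      d <- if (is.na(parent[i])) 0 else depth_of(parent[i]) +
        (if (is.na(brlen[i])) 0 else brlen[i])
      depth[i] <<- d
      d
    }
    for (i in seq_along(keep)) depth_of(i)
    age <- max(depth) - depth
    age[abs(age) < 1e-9 * max(depth)] <- 0
  } else {
    blank <- is.na(age)
    if (any(blank)) {
      has_kid <- tabulate(stats::na.omit(parent), length(keep)) > 0
      age[blank & !has_kid] <- 0   # unannotated tips sit at the present
      if (any(is.na(age))) stop("internal node without an age annotation")
    }
  }
  if (any(is.na(age)) || any(age < 0)) stop("negative or missing node age")
  if (any(is.na(theta))) stop("every node needs a theta attribute")
  # default labels for unnamed internal nodes
  un <- !nzchar(label)
  if (any(un)) label[un] <- paste0("n", which(un))
  species_network(label, age, theta, parent, parent2, phiv)
}
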