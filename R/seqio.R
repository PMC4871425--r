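#' @useDynLib gibbsmsa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rgamma runif rmultinom setNames hclust cutree
#'   as.dist pchisq rbinom rgeom
#' @importFrom utils head tail write.table
NULL

#' Amino-acid alphabet
#'
#' Residues are coded internally as integers `1..20` in alphabetical
#' one-letter order `ACDEFGHIKLMNPQRSTVWY`.  `'X'` and any nonstandard
#' letter map to `NA_integer_` (the UNKNOWN code): unknowns contribute
#' nothing to residue counts and are emitted at background frequency in
#' every likelihood.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.aa_code <- local({
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt(paste(AA_ALPHABET, collapse = ""))] <- seq_len(20L)
  v
})

#' Encode an amino-acid string to integer codes
#'
#' @param x single character string of residues (case-insensitive).
#' @return integer vector with values `1..20` or `NA` for unknown letters.
#' @export
aa_encode <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ints <- utf8ToInt(toupper(x))
  ints[ints < 1L | ints > 127L] <- 127L
  .aa_code[ints]
}

#' Decode integer residue codes to a string
#'
#' `NA` codes decode to `'X'`.
#'
#' @param codes integer vector over `1..20`/`NA`.
#' @export
aa_decode <- function(codes) {
  ch <- ifelse(is.na(codes), "X", AA_ALPHABET[codes])
  paste(ch, collapse = "")
}

#' Construct a sequence set
#'
#' The container for the K input proteins: ids, descriptions and encoded
#' residue vectors.  Ids must be unique and every sequence non-empty.
#'
#' @param ids character vector of unique, nonempty identifiers.
#' @param seqs list of integer residue-code vectors (see [aa_encode()]).
#' @param desc optional character descriptions (defaults to "").
#' @return object of class `seq_set` with elements `ids`, `desc`, `seqs`.
#' @export
seq_set <- function(ids, seqs, desc = NULL) {
  stopifnot(is.character(ids), is.list(seqs), length(ids) == length(seqs))
  if (is.null(desc)) desc <- rep("", length(ids))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  if (any(!nzchar(ids))) stop("empty sequence id")
  nk <- lengths(seqs)
  if (any(nk < 1L)) stop("zero-length sequence: ", ids[which(nk < 1L)[1L]])
  structure(list(ids = ids, desc = desc, seqs = lapply(seqs, as.integer)),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: K=%d sequences, lengths %d..%d\n",
              length(x$ids), min(lengths(x$seqs)), max(lengths(x$seqs))))
  invisible(x)
}

#' Number of sequences in a set
#' @param seqs a `seq_set`.
#' @export
n_seq <- function(seqs) length(seqs$ids)

#' Residue counting function
#'
#' Counts residue types over a set of residue codes, the h() that all
#' column likelihoods are built from.  UNKNOWN (`NA`) residues contribute
#' zero; `weights` (same length as `codes`) scale each residue's
#' contribution (effective counts).
#'
#' @param codes integer residue codes.
#' @param weights optional per-residue real weights (default 1).
#' @return numeric length-20 vector of (weighted) counts.
#' @export
count_residues <- function(codes, weights = NULL) {
  out <- numeric(20L)
  keep <- !is.na(codes)
  if (!any(keep)) return(out)
  codes <- codes[keep]
  if (is.null(weights)) {
    tab <- tabulate(codes, nbins = 20L)
    out <- as.numeric(tab)
  } else {
    weights <- weights[keep]
    for (i in seq_along(codes)) out[codes[i]] <- out[codes[i]] + weights[i]
  }
  out
}

# ---------------------------------------------------------------------------
# FASTA

#' Read unaligned protein sequences from FASTA
#'
#' Nonstandard letters map to the UNKNOWN code and are counted in a
#' message; duplicate ids are de-duplicated by suffixing `.2`, `.3`, ...
#' and reported.  A record with no residues is a parse error naming the
#' header line.
#'
#' @param path FASTA file path.
#' @param quiet suppress log messages.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | TRUE]  # keep structure for line nums
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L)
    stop("not FASTA: no '>' header found in ", path, " (line 1)")
  if (any(!grepl("^\\s*$", lines[seq_len(hdr[1L] - 1L)])))
    stop("not FASTA: content before first header (line 1)")
  ends <- c(hdr[-1L] - 1L, length(lines))
  ids <- character(length(hdr)); desc <- character(length(hdr))
  seqs <- vector("list", length(hdr))
  n_unknown <- 0L
  for (i in seq_along(hdr)) {
    h <- sub("^>\\s*", "", lines[hdr[i]])
    ids[i] <- sub("\\s.*$", "", h)
    desc[i] <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    body <- lines[seq.int(hdr[i] + 1L, length.out = ends[i] - hdr[i])]
    s <- gsub("\\s", "", paste(body, collapse = ""))
    if (!nzchar(s))
      stop(sprintf("zero-length record '%s' (line %d)", ids[i], hdr[i]))
    if (grepl("[^A-Za-z*]", s))
      stop(sprintf("non-FASTA content in record '%s' (line %d)",
                   ids[i], hdr[i]))
    codes <- aa_encode(gsub("\\*", "", s))
    n_unknown <- n_unknown + sum(is.na(codes))
    seqs[[i]] <- codes
  }
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)])) {
      ix <- which(ids == id)
      ids[ix[-1L]] <- paste0(id, ".", seq_along(ix[-1L]) + 1L)
      if (!quiet)
        message("de-duplicated id '", id, "' (", length(ix), " records)")
    }
  }
  if (n_unknown > 0L && !quiet)
    message(n_unknown, " nonstandard residue(s) mapped to UNKNOWN")
  seq_set(ids, seqs, desc)
}

#' Write a sequence set as FASTA
#' @param seqs a `seq_set`.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(seqs$ids)) {
    hdr <- if (nzchar(seqs$desc[k]))
      paste0(">", seqs$ids[k], " ", seqs$desc[k]) else paste0(">", seqs$ids[k])
    s <- aa_decode(seqs$seqs[[k]])
    body <- substring(s, seq(1L, nchar(s), width),
                      pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(hdr, body), con)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Gapped MSA (A2M convention)

#' Construct a gapped MSA
#'
#' Rows use the A2M convention: uppercase = residue in a match column,
#' lowercase = insert/flank residue (unaligned to the model), `'-'` =
#' deletion (match column with no residue).  Every row restricted to
#' uppercase + `'-'` has exactly `w` cells, and de-gapping a row
#' reproduces the original sequence.
#'
#' @param ids sequence ids.
#' @param rows character vector of A2M row strings.
#' @return object of class `gapped_msa` with `ids`, `rows`, `w`.
#' @export
gapped_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows))
  ws <- vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    if (length(ch) && any(!grepl("[A-Za-z.-]", ch)))
      stop("illegal character in MSA row")
    sum(grepl("[A-Z-]", ch))
  }, integer(1L), USE.NAMES = FALSE)
  if (length(unique(ws)) > 1L)
    stop("rows disagree on number of match columns: ",
         paste(unique(ws), collapse = ","))
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 w = ws[1L]),
            class = "gapped_msa")
}

#' @export
print.gapped_msa <- function(x, ...) {
  cat(sprintf("gapped_msa: K=%d sequences, w=%d match columns\n",
              length(x$ids), x$w))
  invisible(x)
}

#' Remove gaps from an A2M row
#'
#' Drops `'-'` (and `'.'`), uppercases and concatenates the remaining
#' residues: the inverse of alignment, recovering the input sequence.
#'
#' @param row A2M row string.
#' @return integer residue-code vector.
#' @export
degap <- function(row) {
  ch <- strsplit(row, "")[[1]]
  bad <- ch[!grepl("[A-Za-z.-]", ch)]
  if (length(bad)) stop("illegal character in row: '", bad[1L], "'")
  ch <- ch[grepl("[A-Za-z]", ch)]
  if (!length(ch)) return(integer(0))
  aa_encode(paste(ch, collapse = ""))
}

#' Write a gapped MSA
#'
#' A2M aligned-FASTA is the default output format: the model is local
#' with respect to each sequence but global with respect to the model,
#' and A2M natively distinguishes unaligned (lowercase) from deleted
#' (`'-'`) positions.  Stockholm 1.0 output carries a `#=GC RF` line with
#' `'x'` marking match columns; insert residues are padded with `'.'`
#' so all rows have equal length.
#'
#' @param msa a `gapped_msa`.
#' @param path output file.
#' @param format `"a2m"` or `"stockholm"`.
#' @export
write_msa <- function(msa, path, format = c("a2m", "stockholm")) {
  format <- match.arg(tolower(format[1L]), c("a2m", "stockholm"))
  con <- file(path, "w"); on.exit(close(con))
  if (format == "a2m") {
    for (k in seq_along(msa$ids))
      writeLines(c(paste0(">", msa$ids[k]), msa$rows[k]), con)
  } else {
    # column-expand: pad each inter-match insert region to its max width
    split_rows <- lapply(msa$rows, .a2m_segments, w = msa$w)
    seg_w <- sapply(split_rows, function(s) nchar(s$ins))  # (w+1) x K
    if (is.null(dim(seg_w))) seg_w <- matrix(seg_w, nrow = msa$w + 1L)
    pad <- apply(seg_w, 1L, max)
    lines <- vapply(split_rows, function(s) {
      ins <- s$ins
      for (i in seq_along(ins))
        ins[i] <- paste0(ins[i],
                         strrep(".", pad[i] - nchar(ins[i])))
      paste0(paste0(ins[-length(ins)], s$match, collapse = ""),
             ins[length(ins)])
    }, character(1L))
    rf <- paste0(paste0(strrep(".", pad[-length(pad)]), "x", collapse = ""),
                 strrep(".", pad[length(pad)]))
    nm <- formatC(msa$ids, width = max(nchar(msa$ids), 10L), flag = "-")
    writeLines("# STOCKHOLM 1.0", con)
    writeLines(paste(nm, lines), con)
    writeLines(paste(formatC("#=GC RF", width = max(nchar(msa$ids), 10L),
                             flag = "-"), rf), con)
    writeLines("//", con)
  }
  invisible(NULL)
}

# split an A2M row into w match cells and w+1 insert segments
.a2m_segments <- function(row, w) {
  ch <- strsplit(row, "")[[1]]
  ch <- ch[ch != "."]
  is_match <- grepl("[A-Z-]", ch)
  match <- ch[is_match]
  ins <- character(w + 1L)
  seg <- 1L
  buf <- character(0)
  for (c in ch) {
    if (grepl("[A-Z-]", c)) {
      ins[seg] <- paste(buf, collapse = ""); buf <- character(0); seg <- seg + 1L
    } else buf <- c(buf, c)
  }
  ins[seg] <- paste(buf, collapse = "")
  list(match = match, ins = ins)
}

#' Read an A2M aligned-FASTA file
#' @param path file path.
#' @return a `gapped_msa`.
#' @export
read_a2m <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("not aligned FASTA: no headers (line 1)")
  ends <- c(hdr[-1L] - 1L, length(lines))
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[hdr]))
  rows <- vapply(seq_along(hdr), function(i) {
    gsub("\\s", "",
         paste(lines[seq.int(hdr[i] + 1L, length.out = ends[i] - hdr[i])],
               collapse = ""))
  }, character(1L))
  gapped_msa(ids, rows)
}

#' Read a Stockholm 1.0 file written by [write_msa()]
#' @param path file path.
#' @return a `gapped_msa` (match columns taken from the `#=GC RF` line).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rf <- grep("^#=GC RF", lines, value = TRUE)
  if (!length(rf)) stop("no #=GC RF line")
  body <- lines[!grepl("^(#|//)|^\\s*$", lines)]
  ids <- trimws(sub("\\s.*$", "", body))
  seqs <- sub("^\\S+\\s+", "", body)
  rf_ch <- strsplit(sub("^#=GC RF\\s+", "", rf[1L]), "")[[1]]
  is_match <- rf_ch == "x"
  rows <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    stopifnot(length(ch) == length(is_match))
    out <- ifelse(is_match, toupper(ch), tolower(ch))
    out[!is_match & ch %in% c(".", "-")] <- ""
    out[is_match & ch == "."] <- "-"
    paste(out, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  gapped_msa(ids, rows)
}

#' Match-column assignment vectors of a gapped MSA
#'
#' For each row returns an integer vector of length `n_k` giving, for
#' every residue, the match column it occupies (0 for insert/flank).
#'
#' @param msa a `gapped_msa`.
#' @return list of integer vectors.
#' @export
msa_assignments <- function(msa) {
  lapply(msa$rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    ch <- ch[ch != "."]
    colidx <- cumsum(grepl("[A-Z-]", ch))
    out <- ifelse(grepl("[A-Z]", ch), colidx, 0L)
    as.integer(out[grepl("[A-Za-z]", ch)])
  })
}
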