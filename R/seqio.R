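#' Load sequences from FASTA or FASTQ
#'
#' Reads DNA sequences from a (possibly gzip-compressed) FASTA or FASTQ file.
#' Sequences are upper-cased, qualities are discarded and duplicate record
#' names are an error: every downstream structure identifies reads by name.
#'
#' @param path Path to the input file; gzip is detected by Biostrings.
#' @param format One of \code{"auto"}, \code{"fasta"}, \code{"fastq"}.
#'   \code{"auto"} inspects the first non-empty character (\code{>} vs
#'   \code{@}).
#' @return A \link[Biostrings]{DNAStringSet} in file order.
#' @export
loadSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    con <- gzfile(path, "r")
    on.exit(close(con), add = TRUE)
    first <- ""
    while (!nzchar(first)) {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L) stop("empty input: ", path)
      first <- trimws(ln)
    }
    format <- if (startsWith(first, ">")) "fasta"
      else if (startsWith(first, "@")) "fastq"
      else stop("cannot determine format of ", path,
                ": first character is neither '>' nor '@'")
  }
  if (format == "fastq") {
    # 4-line-record FASTQ dialect, validated (Biostrings pads short quality
    # strings instead of rejecting them); qualities are discarded
    con2 <- gzfile(path, "r")
    lines <- readLines(con2)
    close(con2)
    while (length(lines) > 0 && !nzchar(lines[length(lines)]))
      lines <- lines[-length(lines)]
    if (length(lines) %% 4 != 0)
      stop("FASTQ parse error: ", length(lines),
           " lines is not a multiple of 4")
    n4 <- length(lines) / 4
    hd <- lines[seq(1, by = 4, length.out = n4)]
    sq <- lines[seq(2, by = 4, length.out = n4)]
    pl <- lines[seq(3, by = 4, length.out = n4)]
    ql <- lines[seq(4, by = 4, length.out = n4)]
    bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                   nchar(sq) != nchar(ql))
    if (length(bad) > 0)
      stop("FASTQ parse error at line ", 4L * (bad[1] - 1L) + 1L,
           ": malformed record (header/separator/quality length)")
    seqs <- Biostrings::DNAStringSet(toupper(sq))
    names(seqs) <- substring(hd, 2)
  } else {
    seqs <- Biostrings::readDNAStringSet(path, format = format)
  }
  # take the name up to the first whitespace, like most tools do
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms))
    stop("duplicate sequence name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(seqs) <- nms
  # normalise case; anything outside ACGTN is not expected from DNAStringSet
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs A \link[Biostrings]{DNAStringSet} or named character vector.
#' @param path Output path (\code{.gz} suffix triggers compression).
#' @param width Line-wrap width, default 80 columns.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path, width = 80L) {
  seqs <- asDNAStringSet(seqs)
  compress <- grepl("\\.gz$", path)
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = width,
                              compress = compress)
  invisible(path)
}

#' Write sequences as FASTQ with constant qualities
#'
#' Assemblies and simulated reads carry no base-quality information, so a
#' constant Q20 ('5') quality string is emitted.
#'
#' @inheritParams writeFasta
#' @export
writeFastq <- function(seqs, path) {
  seqs <- asDNAStringSet(seqs)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  ss <- as.character(seqs)
  for (i in seq_along(ss)) {
    writeLines(c(paste0("@", names(ss)[i]), ss[[i]], "+",
                 strrep("5", nchar(ss[[i]]))), con)
  }
  invisible(path)
}

# normalise any sequence input to an upper-case named DNAStringSet
asDNAStringSet <- function(x) {
  if (is.character(x) && length(x) == 0)
    return(Biostrings::DNAStringSet())
  if (is(x, "DNAStringSet")) {
    out <- x
  } else if (is(x, "DNAString")) {
    out <- Biostrings::DNAStringSet(x)
    if (is.null(names(out))) names(out) <- "seq_1"
  } else if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    if (is.null(names(x)))
      names(out) <- paste0("seq_", seq_along(x))
    else names(out) <- names(x)
  } else stop("cannot interpret input as DNA sequences")
  if (anyDuplicated(names(out))) stop("duplicate sequence names")
  out
}

# plain upper-case character vector with names, for the C++ layer
asSeqChar <- function(x) {
  s <- toupper(as.character(asDNAStringSet(x)))
  s
}

#' Encode a k-mer as an integer code
#'
#' 2-bit encoding with A=0, C=1, G=2, T=3 and the first base in the most
#' significant position, so all 15-mer codes span [0, 2^30). Codes are exact
#' as R doubles for k <= 26; the internal 64-bit encoding supports k up to 31.
#' A k-mer containing any non-ACGT base maps to \code{NA} (never silently
#' encoded).
#'
#' @param kmers Character vector of k-mers, all of length \code{k}.
#' @param k k-mer length (1..31; codes returned to R require k <= 26).
#' @return Numeric vector of codes (NA where invalid).
#' @examples
#' encodeKmer("ACG", 3)  # 0*16 + 1*4 + 2 = 6
#' @export
encodeKmer <- function(kmers, k = nchar(kmers[1])) {
  if (k > 26) stop("codes beyond k = 26 are not exactly representable in R; ",
                   "use the internal 64-bit path")
  out <- olca_encode_kmer(as.character(kmers), as.integer(k))
  if (anyNA(out) && !anyNA(kmers))
    warning("k-mer(s) containing non-ACGT bases encoded as NA")
  out
}

#' Decode a k-mer code back to its sequence
#'
#' @param codes Numeric codes as returned by \code{\link{encodeKmer}}.
#' @param k k-mer length.
#' @return Character vector of k-mers.
#' @export
decodeKmer <- function(codes, k) {
  if (k > 26) stop("codes beyond k = 26 are not exactly representable in R")
  olca_decode_kmer(as.numeric(codes), as.integer(k))
}

# reverse complement for plain character vectors
revcompChar <- function(x) {
  out <- olca_revcomp(as.character(x))
  names(out) <- names(x)
  out
}
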