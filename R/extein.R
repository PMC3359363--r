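#' Extein records and candidate insertion sites
#'
#' An extein record holds a host-protein (extein) sequence together with any
#' annotated native intein insertion sites.  Positions are 1-based indices of
#' the +1 residue: the nucleophilic Cys/Ser/Thr that starts the C-extein and
#' defines an insertion site.  The intein inserts between the -1 and +1
#' residues.
#'
#' @param id character scalar identifier.
#' @param sequence amino-acid sequence (one-letter codes; characters outside
#'   the 20 standard residues are recorded as `X`).
#' @param native_sites integer vector of 1-based +1 positions of known
#'   insertion sites (possibly empty).  Each must index a C, S or T residue.
#' @param source_note free-text provenance note.
#' @return An object of class `extein_record`: a list with elements `id`,
#'   `sequence` (normalized string), `residues` (character vector),
#'   `native_sites` and `source_note`.
#' @examples
#' ex <- extein_record("toy", "MKVLSTAGWCAAS", native_sites = 6)
#' enumerate_candidate_sites(ex)
#' @export
extein_record <- function(id, sequence, native_sites = integer(), source_note = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stopf("'id' must be a non-empty character scalar")
  }
  res <- normalize_residues(split_residues(sequence))
  if (length(res) == 0L) stopf("extein '%s': empty sequence", id)
  native_sites <- as.integer(native_sites)
  if (anyNA(native_sites)) stopf("extein '%s': NA native site position", id)
  bad <- native_sites[native_sites < 1L | native_sites > length(res)]
  if (length(bad)) {
    stopf("extein '%s': native site position %d outside sequence 1..%d",
          id, bad[1L], length(res))
  }
  not_cst <- native_sites[!(res[native_sites] %in% CST)]
  if (length(not_cst)) {
    stopf("extein '%s': native site %d is '%s', not C/S/T",
          id, not_cst[1L], res[not_cst[1L]])
  }
  structure(
    list(id = id,
         sequence = paste(res, collapse = ""),
         residues = res,
         native_sites = sort(unique(native_sites)),
         source_note = source_note),
    class = "extein_record"
  )
}

#' @export
print.extein_record <- function(x, ...) {
  cat(sprintf("<extein_record> %s: %d aa, %d native insertion site(s)\n",
              x$id, length(x$residues), length(x$native_sites)))
  if (length(x$native_sites)) {
    cat("  native +1 sites:",
        paste0(x$residues[x$native_sites], x$native_sites, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read exteins from a FASTA file
#'
#' Native insertion sites are not part of FASTA; they can be encoded in the
#' description line as `sites=12,87` and are parsed when present.
#'
#' @param path path to a FASTA amino-acid file.
#' @return list of [extein_record] objects.
#' @export
read_exteins <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             whole.header = TRUE)
  if (length(seqs) == 0L) stopf("no sequences in %s", path)
  lapply(seqs, function(s) {
    header <- attr(s, "name")
    id <- strsplit(header, "[ \t]+")[[1L]][1L]
    sites <- integer()
    m <- regmatches(header, regexpr("sites=[0-9,]+", header))
    if (length(m) && nzchar(m)) {
      sites <- as.integer(strsplit(sub("sites=", "", m), ",")[[1L]])
    }
    extein_record(id, as.character(s), native_sites = sites,
                  source_note = header)
  })
}

#' Enumerate candidate C/S/T insertion sites
#'
#' Scans an extein for every position whose residue is Cys, Ser or Thr and
#' whose full -3..+4 cassette window lies inside the sequence.  Sites whose
#' window is clipped by a terminus are excluded: the cassette encoding is
#' undefined without all six flanking residues.
#'
#' @param extein an [extein_record].
#' @return data frame with columns `extein_id`, `position` (1-based +1
#'   index, ascending), `plus_one_residue` and `is_native`.
#' @export
enumerate_candidate_sites <- function(extein) {
  stopifnot(inherits(extein, "extein_record"))
  res <- extein$residues
  n <- length(res)
  empty <- data.frame(extein_id = character(), position = integer(),
                      plus_one_residue = character(), is_native = logical(),
                      stringsAsFactors = FALSE)
  if (n < 7L) {
    warnf("extein '%s': sequence shorter than 7 residues, no candidate sites",
          extein$id)
    return(empty)
  }
  pos <- which(res %in% CST)
  pos <- pos[pos >= 4L & pos <= n - 4L]   # full -3..+4 window required
  if (!length(pos)) return(empty)
  data.frame(extein_id = extein$id,
             position = pos,
             plus_one_residue = res[pos],
             is_native = pos %in% extein$native_sites,
             stringsAsFactors = FALSE)
}

#' Extract the insertion-site cassette around a +1 position
#'
#' The cassette is the seven-residue window -3..+4 around an insertion site:
#' three upstream residues, the +1 C/S/T itself, and three downstream
#' residues (+2..+4).
#'
#' @param extein an [extein_record].
#' @param position 1-based index of the +1 residue.
#' @return object of class `cassette`: list with `residues_minus` (length-3
#'   character vector, positions -3..-1), `plus_one`, and `residues_plus`
#'   (positions +2..+4).
#' @examples
#' ex <- extein_record("toy", "MKVLSTAGW")
#' extract_cassette(ex, 5)
#' @export
extract_cassette <- function(extein, position) {
  stopifnot(inherits(extein, "extein_record"))
  res <- extein$residues
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position)) stopf("'position' must be a single integer")
  if (position - 3L < 1L || position + 4L > length(res)) {
    stopf("extein '%s': cassette window %d..%d out of range 1..%d",
          extein$id, position - 3L, position + 4L, length(res))
  }
  if (!(res[position] %in% CST)) {
    stopf("extein '%s': position %d is '%s', not C/S/T",
          extein$id, position, res[position])
  }
  new_cassette(res[(position - 3L):(position - 1L)],
               res[position],
               res[(position + 1L):(position + 3L)])
}

new_cassette <- function(minus, plus_one, plus) {
  minus <- normalize_residues(minus)
  plus <- normalize_residues(plus)
  plus_one <- toupper(plus_one)
  if (length(minus) != 3L || length(plus) != 3L || length(plus_one) != 1L) {
    stopf("a cassette has exactly 3 + 1 + 3 residues")
  }
  if (!(plus_one %in% CST)) stopf("cassette +1 residue must be C, S or T, got '%s'", plus_one)
  structure(list(residues_minus = minus, plus_one = plus_one,
                 residues_plus = plus),
            class = "cassette")
}

#' Build a cassette from a 7-letter string
#'
#' @param x seven residues, centre one being the +1 C/S/T.
#' @return a `cassette` object.
#' @export
as_cassette <- function(x) {
  if (inherits(x, "cassette")) return(x)
  res <- split_residues(x)
  if (length(res) != 7L) stopf("cassette string must have 7 residues, got %d", length(res))
  new_cassette(res[1:3], res[4], res[5:7])
}

#' @export
format.cassette <- function(x, ...) {
  paste0(paste(x$residues_minus, collapse = ""), x$plus_one,
         paste(x$residues_plus, collapse = ""))
}

#' @export
print.cassette <- function(x, ...) {
  cat(sprintf("<cassette> %s-[%s]-%s\n",
              paste(x$residues_minus, collapse = ""), x$plus_one,
              paste(x$residues_plus, collapse = "")))
  invisible(x)
}
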