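#' Define a named residue segment
#'
#' Segments name the structural units the coupling analysis works on: the S4
#' voltage-sensor helix, the S4S5 linker, the pore helices S5/S6 and the
#' selectivity filter. Residue ranges are inclusive at both ends and use the
#' PDB author numbering.
#'
#' @param name segment label, e.g. `"S4"`.
#' @param chain single-letter chain identifier (subunit Mol A-D maps to
#'   chains A-D).
#' @param first,last first and last residue numbers (inclusive).
#' @return A list of class `segment`.
#' @examples
#' segment("S4", "B", 235, 241)
#' @export
segment <- function(name, chain, first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first > last)
    stop("segment '", name, "': need first <= last, got ", first, " > ", last)
  structure(list(name = as.character(name), chain = as.character(chain),
                 first = first, last = last),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("Segment %s: chain %s, residues %d-%d (%d residues)\n",
              x$name, x$chain, x$first, x$last, x$last - x$first + 1L))
  invisible(x)
}

as_segment_list <- function(x) {
  if (inherits(x, "segment")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "segment"))) return(x)
  stop("expected a segment or a list of segments")
}

segment_residues <- function(s) paste0(s$chain, ":", s$first:s$last)

#' Read segment definitions from a text config
#'
#' The config is whitespace-delimited with columns `name chain first last`;
#' lines starting with `#` are comments. The format round-trips through
#' [write_segments()].
#'
#' @param path config file path.
#' @return Named list of [segment()] objects.
#' @export
read_segments <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("name", "chain", "first", "last"),
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  segs <- lapply(seq_len(nrow(tab)), function(i)
    segment(tab$name[i], tab$chain[i], tab$first[i], tab$last[i]))
  names(segs) <- tab$name
  segs
}

#' Write segment definitions to a text config
#' @param segments a list of [segment()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  segments <- as_segment_list(segments)
  lines <- c("# name chain first last",
             vapply(segments, function(s)
               paste(s$name, s$chain, s$first, s$last), ""))
  writeLines(lines, path)
  invisible(path)
}
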