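# Tabular I/O: one dialect everywhere -- tab-separated, UTF-8, header row,
# "NA" for missing.

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsv}}
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", fileEncoding = "UTF-8")
}

# md5 of an object's serialized form (config hashing for stage skipping)
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(character(0))
  md5 <- tools::md5sum(sort(paths))
  stats::setNames(unname(md5), basename(names(md5)))
}
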