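# File formats and run manifests.  Everything is plain TSV/JSON for
# inspectability; posterior draw matrices go to gzip-compressed TSV.

#' Read / write initial (plasmid) count tables
#'
#' TSV with header `guide_id`, `reads`.
#'
#' @param path file path.
#' @return named integer vector of reads per guide / the path, invisibly.
#' @export
read_initial_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("guide_id", "reads"), names(tab))
  if (length(miss)) {
    stop("initial-count table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(tab$reads) | tab$reads < 0)
  if (length(bad)) {
    stop("initial-count table ", path, ": invalid reads at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.integer(tab$reads), tab$guide_id)
}

#' @rdname read_initial_counts
#' @param counts named integer vector.
#' @export
write_initial_counts <- function(counts, path) {
  utils::write.table(data.frame(guide_id = names(counts),
                                reads = as.integer(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a posterior summary table
#'
#' The shared TSV schema produced by both the Bayesian and the frequentist
#' fits.
#'
#' @param x a `FitnessPosterior` or the data frame returned by
#'   [delta_method_fitness()].
#' @param path output TSV path.
#' @export
write_fitness_summary <- function(x, path) {
  tab <- if (inherits(x, "FitnessPosterior")) x$summary else x
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write posterior fitness draws
#'
#' Guides x draws matrix as gzip-compressed TSV (first column `guide_id`).
#'
#' @param posterior a `FitnessPosterior`.
#' @param path output path (`.tsv.gz` recommended).
#' @export
write_fitness_draws <- function(posterior, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(data.frame(guide_id = posterior$guide_id,
                                posterior$f_draws, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a run manifest
#'
#' A JSON record sufficient to re-execute a CLI run bit-identically:
#' command, arguments, seeds, input file checksums and the package version.
#'
#' @param command subcommand name.
#' @param args named list of arguments (file arguments are checksummed).
#' @param path output path; defaults to `<command>_manifest.json` next to
#'   the first output.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(command, args, path) {
  checksums <- list()
  for (nm in names(args)) {
    v <- args[[nm]]
    if (is.character(v) && length(v) == 1 && file.exists(v) && !dir.exists(v)) {
      checksums[[nm]] <- unname(tools::md5sum(v))
    }
  }
  manifest <- list(command = command,
                   package = "clonefit",
                   version = as.character(utils::packageVersion("clonefit")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   args = args,
                   input_md5 = checksums)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
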