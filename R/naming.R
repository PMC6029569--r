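# Strain-name grammar for the collection register.
#
# Virus names look like "1.008.O_10N.286.54.E5" (optionally prefixed with a
# genus label such as "Vibrio phage ", and with an optional "." between the
# lineage letter and the underscore, as printed in the register); host names
# look like "10N.286.54.E5". The numeric size-fraction code encodes both the
# size fraction and the water sample:
#   0.2um: 45,46,47; 1um: 48,49,50; 5um: 51,52,53; 63um: 54,55,56
#   sample A: 45,51,54; sample B: 46,52,55; sample C: 47,53,56.

.fraction_map <- data.frame(
  code = 45:56,
  size_fraction_um = rep(c(0.2, 1, 5, 63), each = 3),
  water_sample = rep(c("A", "B", "C"), times = 4),
  stringsAsFactors = FALSE
)

#' Parse a strain name
#'
#' @param name a virus name (`P.HHH.L_SITE.DAY.CODE.WELL`) or host name
#'   (`SITE.DAY.CODE.WELL`). A leading `"<Genus> phage "` prefix and a dot
#'   between the lineage letter and the underscore are accepted and
#'   preserved for exact re-serialization.
#' @return A `strain_name` object (list) with fields `kind`
#'   ("virus"/"host"), `plaque_id`, `host_working_id`, `lineage`,
#'   `year_site`, `ordinal_day`, `size_fraction_code`, `size_fraction_um`,
#'   `water_sample`, `well`, plus formatting metadata.
#' @export
parse_strain_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  prefix <- ""
  core <- name
  m <- regmatches(name, regexec("^([A-Za-z]+ phage )(.*)$", name))[[1]]
  if (length(m)) {
    prefix <- m[2]
    core <- m[3]
  }
  virus_re <- "^([0-9]+)\\.([0-9A-Za-z]+)\\.([A-Z])(\\.?)_([0-9A-Za-z]+)\\.([0-9]+)\\.([0-9]+)\\.([A-Z][0-9]+)$"
  host_re <- "^([0-9A-Za-z]+)\\.([0-9]+)\\.([0-9]+)\\.([A-Z][0-9]+)$"
  vm <- regmatches(core, regexec(virus_re, core))[[1]]
  if (length(vm)) {
    out <- list(kind = "virus",
                plaque_id = as.integer(vm[2]),
                host_working_id = vm[3],
                lineage = vm[4],
                year_site = vm[6],
                ordinal_day = as.integer(vm[7]),
                size_fraction_code = as.integer(vm[8]),
                well = vm[9],
                prefix = prefix,
                lineage_dot = nzchar(vm[5]))
  } else {
    if (nzchar(prefix)) {
      stop("malformed virus name after phage prefix: '", name, "'")
    }
    hm <- regmatches(core, regexec(host_re, core))[[1]]
    if (!length(hm)) stop("malformed strain name: '", name, "'")
    out <- list(kind = "host",
                plaque_id = NA_integer_,
                host_working_id = NA_character_,
                lineage = NA_character_,
                year_site = hm[2],
                ordinal_day = as.integer(hm[3]),
                size_fraction_code = as.integer(hm[4]),
                well = hm[5],
                prefix = "",
                lineage_dot = FALSE)
  }
  if (out$ordinal_day < 1L || out$ordinal_day > 366L) {
    stop("ordinal_day out of range [1,366] in '", name, "': ",
         out$ordinal_day)
  }
  row <- .fraction_map[.fraction_map$code == out$size_fraction_code, ]
  if (nrow(row) == 0L) {
    stop("unknown size_fraction_code in '", name, "': ",
         out$size_fraction_code)
  }
  out$size_fraction_um <- row$size_fraction_um
  out$water_sample <- row$water_sample
  structure(out, class = "strain_name")
}

#' Re-serialize a parsed strain name to its exact input string
#'
#' @param x a `strain_name` object.
#' @return Character scalar identical to the string originally parsed.
#' @export
format_strain_name <- function(x) {
  stopifnot(inherits(x, "strain_name"))
  tail_part <- sprintf("%s.%d.%d.%s", x$year_site, x$ordinal_day,
                       x$size_fraction_code, x$well)
  if (x$kind == "host") return(tail_part)
  paste0(x$prefix, x$plaque_id, ".", x$host_working_id, ".", x$lineage,
         if (x$lineage_dot) "." else "", "_", tail_part)
}

#' @export
print.strain_name <- function(x, ...) {
  cat(sprintf("<strain_name> %s (%s): day %d, %g um fraction, sample %s, well %s\n",
              format_strain_name(x), x$kind, x$ordinal_day,
              x$size_fraction_um, x$water_sample, x$well))
  invisible(x)
}
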