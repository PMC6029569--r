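# Terminase-archetype assignment.
#
# Every ORF is aligned locally (BLOSUM62, gap open 11 / extend 1) against a
# reference panel of large-terminase (TerL) archetype proteins, each
# labelled with the packaging class it predicts; the best hit under the
# E-value cutoff determines the inferred class. The bundled panel is a
# synthetic stand-in (random proteins carrying the conventional archetype
# names) sufficient for simulation round-trips; users supply a real panel
# for real data via the `refs` argument.

# standard gapped BLOSUM62 Karlin-Altschul parameters (gap 11/1)
.ka_lambda <- 0.267
.ka_K <- 0.041

#' Load the bundled terminase archetype panel
#'
#' @param fasta,class_map optional paths overriding the bundled synthetic
#'   panel (a protein FASTA and a two-column TSV mapping reference_name to
#'   packaging_class).
#' @return data.frame: name, protein, packaging_class.
#' @export
terminase_archetypes <- function(fasta = NULL, class_map = NULL) {
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "synthetic_terl_archetypes.faa",
                         package = "phagestd", mustWork = TRUE)
  }
  if (is.null(class_map)) {
    class_map <- system.file("extdata", "terminase_class_map.tsv",
                             package = "phagestd", mustWork = TRUE)
  }
  aa <- Biostrings::readAAStringSet(fasta)
  cm <- read.delim(class_map, stringsAsFactors = FALSE)
  nm <- sub("\\s.*$", "", names(aa))
  cls <- cm$packaging_class[match(nm, cm$reference_name)]
  if (anyNA(cls)) {
    stop("archetypes missing from class map: ",
         paste(nm[is.na(cls)], collapse = ", "))
  }
  data.frame(name = nm, protein = as.character(aa), packaging_class = cls,
             stringsAsFactors = FALSE)
}

# bit score and E-value from a raw local-alignment score
ka_evalue <- function(raw_score, query_len, db_len) {
  bits <- (.ka_lambda * raw_score - log(.ka_K)) / log(2)
  list(bits = bits, evalue = query_len * db_len * 2^(-bits))
}

#' Assign a terminase archetype to the ORFs of a genome
#'
#' Aligns every ORF protein against every archetype (local alignment,
#' BLOSUM62, gap open 11 / extend 1), converts raw scores to
#' Karlin-Altschul E-values with database size equal to the summed
#' archetype lengths, and returns the best pair under the cutoff; ties on
#' E-value break by higher bit score, then lexicographic reference name.
#'
#' @param orfs data.frame from [find_orfs()].
#' @param refs archetype panel from [terminase_archetypes()].
#' @param evalue_cutoff maximum E-value.
#' @return A `terminase_assignment` list (orf_index, orf, reference_name,
#'   packaging_class, bit_score, evalue), or NULL when no hit passes.
#' @export
assign_terminase <- function(orfs, refs = terminase_archetypes(),
                             evalue_cutoff = 1e-3) {
  stopifnot(nrow(refs) > 0)
  if (!nrow(orfs)) {
    warning("no ORFs supplied; no terminase assignment")
    return(NULL)
  }
  db_len <- sum(nchar(refs$protein))
  subj <- Biostrings::AAStringSet(refs$protein)
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  best <- NULL
  for (i in seq_len(nrow(orfs))) {
    q <- orfs$protein[i]
    if (grepl("X", q, fixed = TRUE)) q <- gsub("X", "A", q)
    scores <- Biostrings::pairwiseAlignment(
      rep(Biostrings::AAStringSet(q), nrow(refs)), subj,
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    ka <- ka_evalue(scores, nchar(q), db_len)
    ord <- order(ka$evalue, -ka$bits, refs$name)
    j <- ord[1L]
    if (ka$evalue[j] < evalue_cutoff &&
        (is.null(best) || ka$evalue[j] < best$evalue ||
           (ka$evalue[j] == best$evalue && ka$bits[j] > best$bit_score))) {
      best <- structure(list(orf_index = i, orf = orfs[i, ],
                             reference_name = refs$name[j],
                             packaging_class = refs$packaging_class[j],
                             bit_score = ka$bits[j],
                             evalue = ka$evalue[j]),
                        class = "terminase_assignment")
    }
  }
  best
}

#' @export
print.terminase_assignment <- function(x, ...) {
  cat(sprintf(
    "<terminase_assignment> ORF %d -> %s (%s), bit %.1f, E = %.3g\n",
    x$orf_index, x$reference_name, x$packaging_class, x$bit_score,
    x$evalue))
  invisible(x)
}
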