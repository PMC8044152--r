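#' Default direction lexicon for the bidirectional screen
#'
#' A lexicon has three parts: `pairs`, generic antonym prefixes applied as
#' `"<term> <axis>"` (e.g. "high ldl cholesterol" -> axis "ldl cholesterol",
#' direction up); `axes`, exact-phrase entries mapping whole disease labels
#' to a named axis and direction (used where the axis is not the literal
#' remainder, e.g. "short QT syndrome" -> QT interval, down); and
#' `exclude`, molecular/cellular/benign phenotype axes that never yield a
#' directional call (enzyme activity, cell permeability, pigmentation, ...).
#'
#' @return a list with elements `pairs`, `axes`, `exclude`.
#' @export
default_direction_lexicon <- function() {
  list(
    pairs = list(
      list(up = "high", down = "low"),
      list(up = "increased", down = "decreased"),
      list(up = "elevated", down = "reduced"),
      list(up = "tall", down = "short"),
      list(up = "long", down = "short"),
      list(up = "hyper", down = "hypo"),
      list(up = "overgrowth", down = "short stature")
    ),
    axes = list(
      "qt interval" = list(up = c("long qt syndrome"),
                           down = c("short qt syndrome")),
      "stature" = list(up = c("tall stature", "overgrowth",
                              "skeletal overgrowth"),
                       down = c("short stature", "idiopathic short stature",
                                "skeletal dysplasia"))
    ),
    exclude = c("enzyme activity", "cell permeability", "pigmentation",
                "protein stability", "membrane potential")
  )
}

validate_lexicon <- function(lexicon) {
  ok <- is.list(lexicon) &&
    all(c("pairs", "axes", "exclude") %in% names(lexicon)) &&
    all(vapply(lexicon$pairs,
               function(p) all(c("up", "down") %in% names(p)), logical(1)))
  if (!ok) stop("malformed direction lexicon: need $pairs (up/down terms), ",
                "$axes and $exclude")
  invisible(lexicon)
}

#' Read / write a direction lexicon as YAML
#'
#' @param path file path.
#' @param lexicon lexicon list as from [default_direction_lexicon()].
#' @return `read_lexicon` returns the validated lexicon.
#' @export
read_lexicon <- function(path) {
  validate_lexicon(yaml::read_yaml(path))
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  validate_lexicon(lexicon)
  yaml::write_yaml(lexicon, path)
  invisible(path)
}

normalize_label <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  gsub("\\s+", " ", trimws(x))
}

#' Classify the phenotypic direction of a disease label
#'
#' Exact-phrase matching after lowercasing and punctuation stripping: first
#' the explicit axis entries, then generic antonym prefixes (the axis is the
#' label with the direction term removed). Labels whose axis is on the
#' exclusion list (molecular/cellular/benign phenotypes) return no call, as
#' do labels with no lexicon hit.
#'
#' @param disease a single free-text disease label.
#' @param lexicon direction lexicon ([default_direction_lexicon()]).
#' @return `NULL` when no call is possible, else a list with `axis`,
#'   `direction` (`"up"`/`"down"`) and `matched_term`.
#' @export
#' @examples
#' classify_direction("high LDL cholesterol")
#' classify_direction("short QT syndrome")
#' classify_direction("increased pigmentation")  # NULL: benign exclusion
classify_direction <- function(disease,
                               lexicon = default_direction_lexicon()) {
  validate_lexicon(lexicon)
  lab <- normalize_label(disease)
  if (nchar(lab) == 0) return(NULL)

  for (axis in names(lexicon$axes)) {
    entry <- lexicon$axes[[axis]]
    for (dir in c("up", "down")) {
      hit <- normalize_label(entry[[dir]]) == lab
      if (any(hit)) {
        if (axis %in% lexicon$exclude) return(NULL)
        return(list(axis = axis, direction = dir,
                    matched_term = entry[[dir]][hit][1]))
      }
    }
  }
  for (pair in lexicon$pairs) {
    for (dir in c("up", "down")) {
      term <- normalize_label(pair[[dir]])
      prefix <- paste0(term, " ")
      if (startsWith(lab, prefix)) {
        axis <- substring(lab, nchar(prefix) + 1)
        if (axis %in% normalize_label(lexicon$exclude)) return(NULL)
        return(list(axis = axis, direction = dir, matched_term = term))
      }
      # glued prefixes such as hyper-/hypo- (hyperglycemia vs hypoglycemia)
      if (!grepl(" ", term) && startsWith(lab, term) &&
          nchar(lab) > nchar(term) && !startsWith(lab, prefix)) {
        axis <- substring(lab, nchar(term) + 1)
        if (axis %in% normalize_label(lexicon$exclude)) return(NULL)
        return(list(axis = axis, direction = dir, matched_term = term))
      }
    }
  }
  NULL
}

#' Screen a mutation catalog for bidirectional-effect genes
#'
#' Collapses the catalog to unique (gene, disease) pairs, drops genes with
#' fewer than `min_diseases` unique disease associations, classifies every
#' surviving label with the direction lexicon, and calls a gene
#' bidirectional when it carries at least one "up" and one "down"
#' association on the same phenotype axis. Genes bidirectional on several
#' axes yield one row per axis. Surviving genes with unclassified labels
#' are exported in a review queue for human curation.
#'
#' @param catalog tibble with columns `gene`, `disease` and optionally
#'   `variant_class`.
#' @param lexicon direction lexicon.
#' @param min_diseases minimum unique disease associations per gene.
#' @param dm_only when `TRUE`, restrict to records whose `variant_class`
#'   is `"DM"` (disease-causing) before any other step.
#' @return list with `best_genes` (tibble: gene, axis, n_up, n_down,
#'   evidence) sorted by gene, and `review_queue` (tibble: gene, disease)
#'   of unclassified labels on surviving genes.
#' @export
call_bidirectional <- function(catalog,
                               lexicon = default_direction_lexicon(),
                               min_diseases = 2, dm_only = FALSE) {
  validate_lexicon(lexicon)
  empty_best <- tibble::tibble(gene = character(), axis = character(),
                               n_up = integer(), n_down = integer(),
                               evidence = list())
  empty_review <- tibble::tibble(gene = character(), disease = character())
  if (is.null(catalog) || nrow(catalog) == 0) {
    warning("empty mutation catalog; returning no calls")
    return(list(best_genes = empty_best, review_queue = empty_review))
  }
  stopifnot(all(c("gene", "disease") %in% names(catalog)))
  if (dm_only) {
    if (!"variant_class" %in% names(catalog)) {
      stop("dm_only = TRUE requires a `variant_class` column")
    }
    catalog <- catalog[catalog$variant_class %in% "DM", , drop = FALSE]
  }
  keep <- !is.na(catalog$gene) & catalog$gene != "" &
    !is.na(catalog$disease) & catalog$disease != ""
  pairs <- dplyr::distinct(catalog[keep, c("gene", "disease")])

  n_dis <- table(pairs$gene)
  surviving <- names(n_dis)[n_dis >= min_diseases]
  pairs <- pairs[pairs$gene %in% surviving, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(list(best_genes = empty_best, review_queue = empty_review))
  }

  calls <- lapply(pairs$disease, classify_direction, lexicon = lexicon)
  classified <- !vapply(calls, is.null, logical(1))
  review <- pairs[!classified, , drop = FALSE]

  if (any(classified)) {
    cls <- tibble::tibble(
      gene = pairs$gene[classified],
      disease = pairs$disease[classified],
      axis = vapply(calls[classified], `[[`, character(1), "axis"),
      direction = vapply(calls[classified], `[[`, character(1), "direction")
    )
    best <- cls |>
      dplyr::group_by(.data$gene, .data$axis) |>
      dplyr::summarise(
        n_up = sum(.data$direction == "up"),
        n_down = sum(.data$direction == "down"),
        evidence = list(sort(.data$disease)),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$n_up >= 1, .data$n_down >= 1) |>
      dplyr::arrange(.data$gene, .data$axis)
  } else {
    best <- empty_best
  }
  list(best_genes = best,
       review_queue = dplyr::arrange(review, .data$gene, .data$disease))
}
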