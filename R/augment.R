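#' Code mapping table
#'
#' A pluggable many-to-many map from source codes to target concepts,
#' optionally weighted (e.g. side-effect frequencies in `[0,1]`). Mapping
#' *content* (PheWAS, GO, pathway, side-effect tables, ICD crosswalks) is
#' always user-supplied; this package ships only the machinery.
#'
#' @param name table name.
#' @param pairs data.frame with columns `source`, `target` and optionally
#'   `weight`.
#' @param target_subdomain the feature subdomain this table populates.
#' @param source_vocab optional label of the source vocabulary.
#' @return Object of class `mapping_table`.
#' @export
mapping_table <- function(name, pairs, target_subdomain, source_vocab = NULL) {
  stopifnot(is.data.frame(pairs), all(c("source", "target") %in% names(pairs)))
  if (nrow(pairs) == 0) stop("mapping table '", name, "' is empty")
  pairs$source <- as.character(pairs$source)
  pairs$target <- as.character(pairs$target)
  if (any(!nzchar(pairs$target))) stop("mapping table '", name, "' has empty targets")
  if ("weight" %in% names(pairs)) {
    if (any(!is.finite(pairs$weight) | pairs$weight < 0 | pairs$weight > 1))
      stop("weights must lie in [0, 1]")
  }
  pairs <- unique(pairs)
  structure(list(name = name, pairs = pairs,
                 target_subdomain = target_subdomain,
                 source_vocab = source_vocab,
                 weighted = "weight" %in% names(pairs)),
            class = "mapping_table")
}

#' Read a mapping table from a delimited file
#'
#' Two columns (`source`, `target`) or three (`source`, `target`, `weight`),
#' tab- or comma-separated, with a header line.
#'
#' @param path file path.
#' @inheritParams mapping_table
#' @return A [mapping_table].
#' @export
read_mapping_table <- function(path, name = basename(path), target_subdomain,
                               source_vocab = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  pairs <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  mapping_table(name, pairs, target_subdomain, source_vocab)
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("mapping_table '%s': %d pairs -> subdomain '%s'%s\n", x$name,
              nrow(x$pairs), x$target_subdomain,
              if (x$weighted) " (weighted)" else ""))
  invisible(x)
}

## a crosswalk must be applicable in one pass: a target that is itself a
## source of a *different* target would need repeated application
check_acyclic <- function(tbl) {
  p <- tbl$pairs
  nonid_sources <- unique(p$source[p$source != p$target])
  bad <- intersect(unique(p$target), nonid_sources)
  if (length(bad))
    stop("mapping table '", tbl$name, "' is chained/cyclic via: ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Map diagnosis codes to PheWAS concepts
#'
#' Translates diagnosis events to higher-level PheWAS concepts, optionally
#' passing ICD-10 codes through a user-supplied ICD-10 to ICD-9 crosswalk
#' first. Several distinct ICD codes mapping to one concept on the same day
#' collapse to a single concept-day occurrence. Unmapped codes are dropped
#' from the output but collected in the `unmapped` attribute, never silently
#' discarded.
#'
#' @param events claim event table; only `kind == "diagnosis"` rows are
#'   mapped.
#' @param icd9_to_phewas [mapping_table] from ICD-9-CM to PheWAS concepts.
#' @param icd10_to_icd9 optional crosswalk [mapping_table]; codes absent from
#'   it are assumed to be ICD-9 already.
#' @return data.frame of concept events (`patient_id`, `day`, `code`), one
#'   row per distinct patient/day/concept, with attribute `unmapped`
#'   (data.frame `code`, `n`).
#' @export
map_diagnoses <- function(events, icd9_to_phewas, icd10_to_icd9 = NULL) {
  stopifnot(inherits(icd9_to_phewas, "mapping_table"))
  check_acyclic(icd9_to_phewas)
  dx <- events[events$kind == "diagnosis", c("patient_id", "day", "code")]
  if (!is.null(icd10_to_icd9)) {
    stopifnot(inherits(icd10_to_icd9, "mapping_table"))
    check_acyclic(icd10_to_icd9)
    xw <- icd10_to_icd9$pairs
    hit <- dx$code %in% xw$source
    translated <- merge(dx[hit, , drop = FALSE], xw,
                        by.x = "code", by.y = "source")
    translated <- data.frame(patient_id = translated$patient_id,
                             day = translated$day, code = translated$target)
    dx <- rbind(dx[!hit, , drop = FALSE], translated)
  }
  mp <- icd9_to_phewas$pairs
  hit <- dx$code %in% mp$source
  un <- dx$code[!hit]
  unmapped <- if (length(un)) as.data.frame(table(code = un), stringsAsFactors = FALSE)
    else data.frame(code = character(0), n = integer(0))
  names(unmapped) <- c("code", "n")
  mapped <- merge(dx[hit, , drop = FALSE], mp, by.x = "code", by.y = "source")
  out <- unique(data.frame(patient_id = mapped$patient_id, day = mapped$day,
                           code = mapped$target, stringsAsFactors = FALSE))
  out <- out[order(out$patient_id, out$day, out$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Expand events into knowledge-derived feature subdomains
#'
#' Fans each event out through a sequence of mapping tables: for every event
#' whose code appears as a table source, one feature event is emitted per
#' mapped target in that table's target subdomain, inheriting the source
#' event's day (and hence its time bin) and prescription duration. Weighted
#' tables emit weighted feature events. The input events themselves are
#' returned as claims-origin feature events in their own subdomain.
#'
#' @param events data.frame `patient_id`, `day`, `code`, plus `subdomain`
#'   naming the claims-origin subdomain each event belongs to (e.g.
#'   `"phewas"`, `"substance"`); optional `duration_days`.
#' @param tables list of [mapping_table]s.
#' @param subdomains optional character vector of declared subdomains; a
#'   table targeting an undeclared subdomain raises an error.
#' @return data.frame of feature events: `patient_id`, `day`, `subdomain`,
#'   `feature`, `weight`, `duration_days`.
#' @export
expand_knowledge <- function(events, tables = list(), subdomains = NULL) {
  stopifnot(all(c("patient_id", "day", "code", "subdomain") %in% names(events)))
  if (!"duration_days" %in% names(events)) events$duration_days <- NA_real_
  base <- data.frame(patient_id = events$patient_id, day = events$day,
                     subdomain = events$subdomain, feature = events$code,
                     weight = 1, duration_days = events$duration_days,
                     stringsAsFactors = FALSE)
  out <- list(base)
  for (tbl in tables) {
    stopifnot(inherits(tbl, "mapping_table"))
    if (!is.null(subdomains) && !tbl$target_subdomain %in% subdomains)
      stop("mapping table '", tbl$name, "' targets undeclared subdomain '",
           tbl$target_subdomain, "'")
    mp <- tbl$pairs
    hit <- events$code %in% mp$source
    if (!any(hit)) next
    joined <- merge(events[hit, c("patient_id", "day", "code", "duration_days")],
                    mp, by.x = "code", by.y = "source")
    out[[length(out) + 1L]] <- data.frame(
      patient_id = joined$patient_id, day = joined$day,
      subdomain = tbl$target_subdomain, feature = joined$target,
      weight = if (tbl$weighted) joined$weight else 1,
      duration_days = joined$duration_days, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$day, res$subdomain, res$feature), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

## canonical domain for the claims-origin subdomain names; anything else must
## be declared via domain_of
default_domains <- c(phewas = "diagnosis", biomarker = "diagnosis",
                     go_term_dx = "diagnosis", mesh = "diagnosis",
                     pathway_dx = "diagnosis", symptoms = "diagnosis",
                     substance = "drug", go_term_rx = "drug",
                     pathway_rx = "drug", indications = "drug",
                     side_effects = "drug", target_tissue = "drug",
                     therapeutic_class = "drug", therapeutic_group = "drug")

#' Build the hierarchical feature schema
#'
#' Assembles the domain -> subdomain -> feature hierarchy from a claims-origin
#' vocabulary, a set of augmentation mapping tables, and static (general
#' domain) features. Feature ordering is deterministic (lexicographic within
#' subdomain). Diagnosis/drug subdomains are time-dependent; general
#' subdomains are static.
#'
#' @param vocabulary named list: claims-origin subdomain name -> character
#'   feature vocabulary (e.g. `list(phewas = ..., substance = ...)`),
#'   typically the survivors of [prefilter_codes].
#' @param tables list of [mapping_table]s contributing augmented subdomains;
#'   their feature sets are the distinct mapping targets.
#' @param static named list: general-domain subdomain name -> character
#'   feature names (e.g. `list(demographics = c("age", "sex:M", ...))`).
#' @param domain_of named character vector mapping subdomain names to domains
#'   (`"diagnosis"`, `"drug"`, `"general"`); defaults cover the canonical
#'   subdomain names, static subdomains default to `"general"`.
#' @return Object of class `feature_schema`: list of subdomain descriptors
#'   (`name`, `domain`, `features`, `time_dependent`, `origin`, `weighted`).
#' @export
build_schema <- function(vocabulary, tables = list(), static = list(),
                         domain_of = default_domains) {
  subs <- list()
  add <- function(name, domain, features, time_dependent, origin, weighted = FALSE) {
    features <- sort(unique(as.character(features)))
    if (length(features) == 0) stop("subdomain '", name, "' has an empty vocabulary")
    if (name %in% names(subs)) stop("duplicate subdomain '", name, "'")
    subs[[name]] <<- list(name = name, domain = domain, features = features,
                          time_dependent = time_dependent, origin = origin,
                          weighted = weighted)
  }
  if (length(vocabulary) == 0 && length(static) == 0)
    stop("empty vocabulary: nothing to build a schema from")
  for (nm in names(vocabulary)) {
    dom <- domain_of[nm]
    if (is.na(dom)) stop("no domain declared for subdomain '", nm, "'")
    add(nm, unname(dom), vocabulary[[nm]], time_dependent = TRUE,
        origin = "claims")
  }
  for (tbl in tables) {
    dom <- domain_of[tbl$target_subdomain]
    if (is.na(dom)) stop("no domain declared for subdomain '",
                         tbl$target_subdomain, "'")
    add(tbl$target_subdomain, unname(dom), tbl$pairs$target,
        time_dependent = TRUE, origin = "augmented", weighted = tbl$weighted)
  }
  for (nm in names(static)) {
    dom <- if (!is.na(domain_of[nm])) unname(domain_of[nm]) else "general"
    add(nm, dom, static[[nm]], time_dependent = FALSE, origin = "claims")
  }
  structure(list(subdomains = subs), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  d <- schema_dims(x)
  cat("feature_schema:", nrow(d), "subdomains,",
      sum(d$n_features[d$time_dependent]), "time-dependent +",
      sum(d$n_features[!d$time_dependent]), "static features\n")
  print(d, row.names = FALSE)
  invisible(x)
}

#' Schema dimension summary
#'
#' @param schema a `feature_schema`.
#' @return data.frame with one row per subdomain: `domain`, `subdomain`,
#'   `origin`, `time_dependent`, `n_features`.
#' @export
schema_dims <- function(schema) {
  do.call(rbind, lapply(schema$subdomains, function(s)
    data.frame(domain = s$domain, subdomain = s$name, origin = s$origin,
               time_dependent = s$time_dependent,
               n_features = length(s$features))))
}

## subdomain names grouped by domain, fixed order
schema_domains <- function(schema) {
  doms <- unique(vapply(schema$subdomains, `[[`, "", "domain"))
  doms <- doms[order(match(doms, c("diagnosis", "drug", "general")))]
  stats::setNames(lapply(doms, function(d)
    names(Filter(function(s) s$domain == d, schema$subdomains))), doms)
}

#' Serialize / deserialize a feature schema
#'
#' The schema (including explicit feature order) round-trips bit-exactly
#' through a JSON file.
#'
#' @param schema a `feature_schema`.
#' @param path file path.
#' @return `write_schema` returns `path` invisibly; `read_schema` the schema.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(schema$subdomains, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  subs <- jsonlite::read_json(path, simplifyVector = TRUE)
  subs <- lapply(subs, function(s) {
    s$features <- as.character(s$features)
    s
  })
  structure(list(subdomains = subs), class = "feature_schema")
}

## stable content hash (md5 of the canonical JSON serialization)
schema_hash <- function(schema) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(schema$subdomains, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
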