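# Policy-review procedure: keyword identification of fruit/vegetable
# targeting policies, expansion of regional-bloc records to member
# countries, mapping of policy-taxonomy categories onto the Nuffield
# intervention ladder, and region x rung tabulation.

#' The Nuffield intervention ladder
#'
#' Ordered from least to most forceful: provide information; enable
#' choice; guide choice by changing default; guide choice with incentives;
#' guide choice with disincentives; restrict choice; eliminate choice.
#'
#' @return Character vector of the seven rungs in ladder order.
#' @export
nuffield_rungs <- function() {
  c("provide information",
    "enable choice",
    "guide choice by changing default",
    "guide choice with incentives",
    "guide choice with disincentives",
    "restrict choice",
    "eliminate choice")
}

#' The shipped policy taxonomy with its Nuffield mapping
#'
#' A synthetic stand-in for a full policy-framework category table: policy
#' categories grouped into three domains (food environment, food
#' system/supply, behaviour change communication), each mapped to exactly
#' one Nuffield rung. The mapping lives in an editable CSV data file
#' (`extdata/nourishing_to_nuffield.csv`), not in code; totality and rung
#' validity are asserted at load time. Three rows follow established
#' precedent: store-owner location incentives map to "enable choice"
#' (the consumer-side effect is wider access, not an incentive to the
#' consumer), dietary guidelines to "provide information", and fiscal
#' price-reduction policies to "guide choice with incentives".
#'
#' @param path Optional path to an alternative mapping CSV with columns
#'   `domain`, `category`, `rung`.
#' @return data.frame with columns `domain`, `category`, `rung`.
#' @export
nourishing_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nourishing_to_nuffield.csv",
                        package = "fvgap")
  }
  tax <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("domain", "category", "rung")
  if (!all(need %in% names(tax))) {
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tax$category)) {
    stop("taxonomy error: category mapped to more than one rung: ",
         paste(unique(tax$category[duplicated(tax$category)]), collapse = ", "))
  }
  bad <- setdiff(tax$rung, nuffield_rungs())
  if (length(bad) > 0) {
    stop("taxonomy error: unknown rung(s): ", paste(bad, collapse = ", "))
  }
  tax
}

#' Keyword filter for fruit/vegetable-targeting policies
#'
#' Case-insensitive substring match of the keywords against record
#' descriptions ("fruit" also matches "fruits", etc.). Records that speak
#' only of general healthy eating, with no keyword hit, are excluded.
#' Adding keywords can only grow the matched set.
#'
#' @param records Policy data.frame with a `description` column.
#' @param keywords Keywords to match (default `"fruit"`, `"vegetable"`).
#' @param word_boundary If `TRUE`, require the keyword to start at a word
#'   boundary instead of matching any substring.
#' @return The matching subset of `records`.
#' @export
filter_fv_policies <- function(records, keywords = c("fruit", "vegetable"),
                               word_boundary = FALSE) {
  if (nrow(records) == 0 || length(keywords) == 0) {
    return(records[integer(0), , drop = FALSE])
  }
  desc <- tolower(records$description)
  hit <- rep(FALSE, nrow(records))
  for (kw in tolower(keywords)) {
    if (word_boundary) {
      hit <- hit | grepl(paste0("\\b", kw), desc, perl = TRUE)
    } else {
      hit <- hit | grepl(kw, desc, fixed = TRUE)
    }
  }
  records[hit, , drop = FALSE]
}

#' Expand regional-bloc records to country level
#'
#' Records whose jurisdiction is a bloc become one record per member
#' country (the policy is assumed implemented by every member); country
#' records pass through unchanged. A `source_bloc` column retains
#' provenance.
#'
#' @param records Policy data.frame with a `jurisdiction` column.
#' @param membership Named list, bloc name -> member country codes; see
#'   [default_region_membership()].
#' @param countries Optional vector of known country codes; if given, any
#'   jurisdiction that is neither a bloc nor a known country raises a
#'   membership error.
#' @return Country-level data.frame with columns of `records` plus
#'   `country` and `source_bloc` (`NA` for native country records).
#' @export
expand_regions <- function(records, membership = default_region_membership(),
                           countries = NULL) {
  is_bloc <- records$jurisdiction %in% names(membership)
  if (!is.null(countries)) {
    unknown <- !is_bloc & !(records$jurisdiction %in% countries)
    if (any(unknown)) {
      stop("membership error: unknown bloc or country jurisdiction(s): ",
           paste(unique(records$jurisdiction[unknown]), collapse = ", "))
    }
  }
  native <- records[!is_bloc, , drop = FALSE]
  if (nrow(native) > 0) {
    native$country <- native$jurisdiction
    native$source_bloc <- NA_character_
  }
  expanded <- lapply(which(is_bloc), function(r) {
    members <- membership[[records$jurisdiction[r]]]
    out <- records[rep(r, length(members)), , drop = FALSE]
    out$country <- members
    out$source_bloc <- records$jurisdiction[r]
    out
  })
  out <- do.call(rbind, c(list(native), expanded))
  if (is.null(out)) out <- cbind(records, country = character(0),
                                 source_bloc = character(0))
  rownames(out) <- NULL
  out
}

#' Map policy categories to Nuffield rungs
#'
#' Total function over the shipped taxonomy: every category maps to
#' exactly one rung.
#'
#' @param category Character vector of taxonomy categories.
#' @param taxonomy Mapping table from [nourishing_taxonomy()].
#' @return Character vector of rungs, same length as `category`.
#' @export
#' @examples
#' map_to_nuffield("food-based dietary guidelines")
map_to_nuffield <- function(category, taxonomy = nourishing_taxonomy()) {
  rung <- taxonomy$rung[match(category, taxonomy$category)]
  if (anyNA(rung)) {
    stop("taxonomy error: unknown category(ies): ",
         paste(unique(category[is.na(rung)]), collapse = "; "),
         ". Valid categories: ",
         paste(taxonomy$category, collapse = "; "))
  }
  rung
}

#' Tabulate country-level policy records by region and Nuffield rung
#'
#' Counts distinct countries (not records, unless `count = "policies"`)
#' per region x rung, reporting every rung of the ladder — rungs with no
#' observed policies appear as zero rows. Also returns totals by policy
#' domain.
#'
#' @param records Country-level policy data.frame (see [expand_regions()])
#'   with columns `country`, `category`, `domain`.
#' @param region_map data.frame `country`, `region` covering every country
#'   appearing in `records`.
#' @param taxonomy Category -> rung mapping table.
#' @param count Count "countries" (distinct, the default) or "policies"
#'   (records).
#' @return List with `by_region_rung` (region, rung, n; full rung index)
#'   and `by_domain` (domain, n).
#' @export
tabulate_policies <- function(records, region_map,
                              taxonomy = nourishing_taxonomy(),
                              count = c("countries", "policies")) {
  count <- match.arg(count)
  rungs <- nuffield_rungs()
  regions <- sort(unique(region_map$region))
  grid <- expand.grid(region = regions, rung = rungs,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$region, match(grid$rung, rungs)), ]
  rownames(grid) <- NULL
  grid$n <- 0L
  dom_tab <- data.frame(domain = sort(unique(taxonomy$domain)), n = 0L,
                        stringsAsFactors = FALSE)
  if (nrow(records) > 0) {
    unmapped <- setdiff(records$country, region_map$country)
    if (length(unmapped) > 0) {
      stop("grouping error: country(ies) without region assignment: ",
           paste(unmapped, collapse = ", "))
    }
    records$rung <- map_to_nuffield(records$category, taxonomy)
    records$region <- region_map$region[match(records$country,
                                              region_map$country)]
    dt <- table(records$domain)  # domain totals count records, not countries
    dom_tab$n[match(names(dt), dom_tab$domain)] <- as.integer(dt)
    if (count == "countries") {
      records <- records[!duplicated(records[, c("country", "rung")]), ]
    }
    tb <- aggregate(list(n = records$country),
                    by = list(region = records$region, rung = records$rung),
                    FUN = length)
    key <- paste(grid$region, grid$rung)
    hit <- match(paste(tb$region, tb$rung), key)
    grid$n[hit] <- tb$n
  }
  list(by_region_rung = grid, by_domain = dom_tab)
}
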