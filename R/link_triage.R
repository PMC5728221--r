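# Website-category triage of extracted hyperlinks, and inter-annotator
# agreement. No live HTTP fetching or WHOIS: link features arrive as
# structured records filled in by a human coder (or by fixtures in tests).

LINK_CATEGORIES <- c("classified_ad", "online_pharmacy", "unclassifiable",
                     "pending")
PLATFORM_KINDS <- c("classifieds", "pharmacy_storefront", "forum", "other",
                    "unknown")

#' Build a link-feature record
#'
#' @param url the hyperlink.
#' @param platform_kind one of `"classifieds"`, `"pharmacy_storefront"`,
#'   `"forum"`, `"other"`, `"unknown"`.
#' @param offers_no_prescription site sells prescription drugs with no
#'   prescription required.
#' @param has_drug_price_list site posts per-unit drug prices.
#' @param redirect_unresolved traffic redirection prevented resolution
#'   (forces `resolved = FALSE`).
#' @return A one-row tibble with `category = "pending"`.
#' @export
link_record <- function(url, platform_kind = "unknown",
                        offers_no_prescription = FALSE,
                        has_drug_price_list = FALSE,
                        redirect_unresolved = FALSE) {
  platform_kind <- match.arg(platform_kind, PLATFORM_KINDS)
  tibble::tibble(url = url,
                 platform_kind = platform_kind,
                 offers_no_prescription = offers_no_prescription,
                 has_drug_price_list = has_drug_price_list,
                 redirect_unresolved = redirect_unresolved,
                 resolved = !redirect_unresolved,
                 category = "pending",
                 reason = NA_character_)
}

#' Read link-feature records from CSV
#'
#' Expected columns: `url`, `platform_kind`, `offers_no_prescription`,
#' `has_drug_price_list`, `redirect_unresolved` (logicals as TRUE/FALSE).
#'
#' @param path CSV path.
#' @return Tibble of pending link records.
#' @export
read_link_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("url", "platform_kind", "offers_no_prescription",
            "has_drug_price_list", "redirect_unresolved")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("link feature file missing column(s): ",
         paste(missing, collapse = ", "))
  }
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    link_record(df$url[i], df$platform_kind[i],
                as.logical(df$offers_no_prescription[i]),
                as.logical(df$has_drug_price_list[i]),
                as.logical(df$redirect_unresolved[i]))
  }))
}

#' Triage one link record into a website category
#'
#' Fixed rule order: (1) unresolved redirection is unclassifiable (and wins
#' over any pharmacy features, with the conflict logged); (2) a classifieds
#' platform is a classified ad; (3) a pharmacy storefront, no-prescription
#' offer or posted drug price list is an online pharmacy; (4) otherwise
#' unclassifiable for lack of features.
#'
#' @param record a one-row link-record tibble.
#' @return The record with `category` and `reason` filled in.
#' @export
classify_link <- function(record) {
  pharmacy_signal <- record$platform_kind == "pharmacy_storefront" ||
    isTRUE(record$offers_no_prescription) ||
    isTRUE(record$has_drug_price_list)
  if (isTRUE(record$redirect_unresolved)) {
    if (pharmacy_signal) {
      warning("link ", record$url,
              ": unresolved redirect wins over pharmacy features")
    }
    record$category <- "unclassifiable"
    record$reason <- "traffic redirection unresolved"
  } else if (record$platform_kind == "classifieds") {
    record$category <- "classified_ad"
    record$reason <- "classifieds platform"
  } else if (pharmacy_signal) {
    record$category <- "online_pharmacy"
    record$reason <- "pharmacy storefront / no-prescription / price list"
  } else {
    record$category <- "unclassifiable"
    record$reason <- "insufficient features"
  }
  record
}

#' Triage a table of link records
#'
#' @param links tibble of link records (one per row).
#' @return The table with every row triaged.
#' @export
triage_links <- function(links) {
  if (nrow(links) == 0L) return(links)
  do.call(rbind, lapply(seq_len(nrow(links)),
                        function(i) classify_link(links[i, , drop = FALSE])))
}

#' Tabulate triaged link categories
#'
#' @param links fully triaged link records (no `"pending"` rows).
#' @return Named integer vector over `classified_ad`, `online_pharmacy`,
#'   `unclassifiable`; sums to `nrow(links)`.
#' @export
tabulate_categories <- function(links) {
  if (nrow(links) > 0L && any(links$category == "pending")) {
    stop("pending (untriaged) links present; run triage_links() first")
  }
  cats <- setdiff(LINK_CATEGORIES, "pending")
  counts <- vapply(cats, function(cc) sum(links$category == cc), integer(1))
  counts
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with `p_o`
#' the observed agreement fraction and `p_e` the expected agreement from the
#' two annotators' marginal label proportions. Accepts either a square
#' confusion matrix or two label vectors. When both annotators are constant
#' and identical (`p_e = 1`) kappa is defined as 1 with a warning.
#'
#' @param x square confusion matrix (annotator A in rows, B in columns), or
#'   a vector of annotator A's labels.
#' @param y annotator B's labels when `x` is a vector.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(x, y = NULL) {
  if (is.matrix(x)) {
    cm <- x
  } else {
    stopifnot(!is.null(y), length(x) == length(y), length(x) >= 1L)
    levels_all <- sort(unique(c(as.character(x), as.character(y))))
    cm <- table(factor(as.character(x), levels = levels_all),
                factor(as.character(y), levels = levels_all))
    cm <- unclass(cm)
  }
  n <- sum(cm)
  if (n < 1L) stop("empty annotation table")
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    warning("both annotators constant and identical; kappa defined as 1")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Read a two-annotator label file
#'
#' CSV with columns `item_id`, `annotator_a`, `annotator_b`; both label
#' columns must be complete.
#'
#' @param path CSV path.
#' @return Tibble with the three columns.
#' @export
read_annotation_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "annotator_a", "annotator_b")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  }
  if (anyNA(df$annotator_a) || anyNA(df$annotator_b)) {
    stop("annotation columns must be complete")
  }
  tibble::as_tibble(df[need])
}
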