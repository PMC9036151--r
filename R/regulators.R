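#' Reference table of EU/EEA national competent authorities
#'
#' One row per national regulator active on the EUCTR as of December 2020,
#' with the date the regulator's first record was entered into the EudraCT
#' backend and the number of public country protocols it held at that
#' census. Germany has two independent regulators (BfArM and PEI) sharing
#' country code `DE`; they are distinct audit units throughout. The United
#' Kingdom is included: its data remained comparable to EU peers up to that
#' census.
#'
#' The earliest-record date per country is the "link date" used by the
#' expected-protocol rule: a country can only be expected to hold a public
#' protocol for trials that started after its regulator was linked to the
#' registry backend. The protocol counts serve as realistic default
#' sampling weights for the synthetic generator.
#'
#' @return a tibble with columns `regulator_id`, `country` (ISO-3166-1
#'   alpha-2), `name`, `earliest_record_date` (`Date`, `NA` where the
#'   regulator never entered a record), `n_protocols`.
#' @export
#' @examples
#' euctr_regulators()
euctr_regulators <- function() {
  tibble::tribble(
    ~regulator_id, ~country, ~name,                                                          ~earliest_record_date, ~n_protocols,
    "BASG",        "AT", "Austrian Federal Office for Safety in Health Care",                 "2004-07-16",  4146L,
    "FAMHP",       "BE", "Federal Agency for Medicines and Health Products",                  "2004-07-07",  5946L,
    "BDA",         "BG", "Bulgarian Drug Agency",                                             "2007-02-02",  2007L,
    "MIZ",         "HR", "Croatian Ministry of Health",                                       "2014-01-24",   401L,
    "MOHPS",       "CY", "Ministry of Health Pharmaceutical Services",                        "2009-02-24",     5L,
    "SUKL-CZ",     "CZ", "State Institute for Drug Control (Czech Republic)",                 "2004-06-24",  4304L,
    "DKMA",        "DK", "Danish Medicines Agency",                                           "2004-08-10",  4069L,
    "SAM",         "EE", "Republic of Estonia Agency of Medicines",                           "2004-11-26",  1020L,
    "FIMEA",       "FI", "Finnish Medicines Agency",                                          "2004-05-26",  2533L,
    "ANSM",        "FR", "Agence Nationale de Securite du Medicament et des Produits de Sante", "2005-06-21", 5852L,
    "BfArM",       "DE", "Federal Institute for Drugs and Medical Devices",                   "2004-09-16",  8324L,
    "PEI",         "DE", "Paul-Ehrlich Institut",                                             "2004-09-10",  3193L,
    "EOF",         "GR", "National Organization for Medicines",                               "2005-11-04",  1791L,
    "OGYEI",       "HU", "National Institute of Pharmacy & Nutrition",                        "2004-06-15",  4473L,
    "IMA",         "IS", "Icelandic Medicines Agency",                                        "2004-09-07",   133L,
    "HPRA",        "IE", "Health Products Regulatory Authority",                              "2004-06-18",  1169L,
    "AIFA",        "IT", "Italian Medicines Agency",                                          "2004-07-16",  7559L,
    "ZVA",         "LV", "State Agency of Medicines of the Republic of Latvia",               "2004-08-03",  1079L,
    "AG",          "LI", "Amt fur Gesundheit",                                                NA_character_,     0L,
    "VVKT",        "LT", "State Medicines Control Agency",                                    "2004-06-22",  1237L,
    "MS",          "LU", "Ministere de la Sante",                                             "2013-07-26",     8L,
    "MDA",         "MT", "Medicines Authority",                                               "2005-10-10",    18L,
    "CCMO",        "NL", "Centrale Commissie Mensgebonden Onderzoek",                         "2006-03-16",  5692L,
    "NOMA",        "NO", "Norwegian Medicines Agency",                                        "2004-05-25",   683L,
    "URPL",        "PL", "Office for Registration of Medicinal Products",                     "2007-03-29",  3242L,
    "INFARMED",    "PT", "Infarmed",                                                          "2005-08-18",  1591L,
    "ANMDM",       "RO", "National Agency for Medicines and Medical Devices",                 "2009-07-14",   239L,
    "SUKL-SK",     "SK", "State Institute for Drug Control (Slovakia)",                       "2004-06-02",  1791L,
    "JAZMP",       "SI", "Agency for Medicinal Products and Medical Devices",                 "2005-06-13",   388L,
    "AEMPS",       "ES", "Agencia Espanola de Medicamentos y Productos Sanitarios",           "2004-06-14",  9566L,
    "MPA",         "SE", "Medical Products Agency",                                           "2004-05-13",  3893L,
    "MHRA",        "GB", "Medicines and Healthcare Products Regulatory Agency",               "2004-07-01", 10975L
  ) |>
    dplyr::mutate(earliest_record_date = as.Date(.data$earliest_record_date))
}
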