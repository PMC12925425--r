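Package: gistar
Title: Local Getis-Ord Gi* Segregation Statistics for Census Tracts
Version: 0.1.0
Authors@R: person("NU", "SocEnvLab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the local Getis-Ord Gi* ("G-i-star") statistic for
    residential segregation at the census-tract level. Builds queen or rook
    contiguity weights directly from tract polygons (GeoJSON or ESRI
    Shapefile), row-standardizes them with the focal tract self-included,
    assigns each tract a larger reference unit (a core-based statistical
    area when the tract falls inside one, otherwise its county), and
    returns a standardized Z-score per tract and population group, with
    reserved negative indicator codes for tracts where the statistic is
    undefined. Includes a deterministic synthetic-lattice fixture generator
    so the full pipeline is testable without any census download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
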