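Package: pvrank
Title: Ranking the Importance of Physiological Variables for ICU Diseases
Version: 0.1.0
Authors@R:
    person("pvrank", "developers", email = "pvrank@example.org", role = c("aut", "cre"))
Author: pvrank developers [aut, cre]
Maintainer: pvrank developers <pvrank@example.org>
Description: A decision-support analysis pipeline that ranks the importance of
    physiological variables (PVs) for intensive-care diseases. Disease
    classifiers (penalized logistic regression on hand-engineered time-series
    summary features) are trained under the full PV catalog and under n
    leave-one-PV-out catalogs; PVs are ranked per disease by the drop in
    held-out AUROC caused by their removal. Includes a synthetic ICU cohort
    generator with planted disease-PV effect sizes so that the whole pipeline,
    including recovery of the planted importance order, is testable without
    access-controlled clinical databases; an ETL layer for cohort selection
    and event cleaning; and disease-similarity comparison of rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
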