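# Study-setting profiles for the four participating hospitals.
# target_fall_rate is events per 1000 hospital-days; n_admissions and
# mean_los_days reproduce the retrospective cohort scale (hospital days /
# admissions). The coverage fixture restricts each site's recordable
# intervention vocabulary to its mapped catalog statements.
sites:
  - site_id: A
    heuristic_tool: hendrich2
    n_drug_classes: 4
    kpcs_available: true
    target_fall_rate: 1.95
    n_admissions: 14307
    mean_los_days: 8.54
    coverage_fixture: mapping_site_A.csv
  - site_id: B
    heuristic_tool: stratify
    n_drug_classes: 11
    kpcs_available: true
    target_fall_rate: 1.69
    n_admissions: 21172
    mean_los_days: 8.15
    coverage_fixture: mapping_site_B.csv
  - site_id: C
    heuristic_tool: morse
    n_drug_classes: 7
    kpcs_available: true
    target_fall_rate: 1.25
    n_admissions: 31930
    mean_los_days: 9.22
    coverage_fixture: mapping_site_C.csv
  - site_id: D
    heuristic_tool: morse
    n_drug_classes: 8
    kpcs_available: false
    target_fall_rate: 1.77
    n_admissions: 36314
    mean_los_days: 8.15
    coverage_fixture: mapping_site_D.csv
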