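# Declarative rule table for the probable/possible-CBD diagnostic criteria
# (criteria parts B and C of the consensus criteria). Kept as data so the
# clinically loaded content is auditable and swappable without code changes.
version: 1
gates:
  insidious_onset_required: true
  min_duration_years: 1
probable_cbd:
  min_age_years: 50
  family_history_allowed: false
  tau_mutation_allowed: false
  # phenotype routes: probable CBS, or FBS/NAV plus >=1 CBS core feature (a)-(f)
  routes: [probable_cbs, fbs_or_nav_plus_core_a_f]
possible_cbd:
  # phenotype routes: possible CBS, FBS, NAV, or PSPS plus >=1 core feature (b)-(f)
  routes: [possible_cbs, fbs, nav, psps_plus_core_b_f]
exclusions:
  - lewy_body_evidence
  - msa_evidence
  - als_evidence
  - semantic_or_logopenic_ppa
  - structural_lesion
  - grn_mutation_or_low_progranulin
  - tdp43_or_fus_mutation
  - ad_biomarker_evidence
# fixed precedence for the single primary label; FBS and NAV co-occurring
# without a CBD diagnosis are reported as FBS_NAV_overlap
precedence:
  - probable_CBD
  - possible_CBD
  - probable_CBS
  - possible_CBS
  - FBS_NAV_overlap
  - FBS
  - NAV
  - PSPS
  - none
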