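# Register dialect reference

The synthetic renderers emulate the *structure* of the four registers'
public record exports — nesting, array placement and field names — at the
granularity the harmonised trial concepts need. They are deliberately not
full schemas: the real registers' complete data models are external,
continually evolving artefacts, and what matters for this package is that
each register's own data model is retained end to end. Field names follow
the registers' public conventions where those are well known (e.g. the
protocol/results section split and module names of the CTGOV v2 API, the
`externalRefs`/`trialDesign`/`participants` blocks of ISRCTN XML, EUCTR's
per-member-state records and yes/no phase flags); the remainder is a frozen
reconstruction. All record-level detail here is reconstructed — the source
registers publish formats and counts, not stable documented record schemas —
so treat this file, not any external schema, as the contract tests rely on.

## Wire formats

| register | format | envelope                                   | records per trial |
|----------|--------|--------------------------------------------|-------------------|
| CTGOV    | JSON   | `{"studies": [ ... ]}`                      | 1                 |
| CTIS     | JSON   | `{"data": [ ... ]}`                         | 1                 |
| EUCTR    | XML    | `<trials><trial country="BE">...</trial>...` | one per member state, `_id` = EudraCT number + `-MS` |
| ISRCTN   | XML    | `<allTrials totalCount="N"><fullTrial><trial>...` | 1           |

XML maps onto the canonical document tree deterministically: repeated
sibling elements become ordered arrays, attributes become `"@"`-prefixed
fields, and mixed content is rejected.

## Field paths consulted by the concept calculators

Every path required by a concept in `concept_registry()` is listed below for
the register it applies to. Paths marked optional need not occur in every
record (calculators are total over missing input). `lastKnownStatus` and
`whyStopped` (CTGOV) are optional refinement fields; results-related paths
occur only in records loaded with results.

### CTGOV
- `hasResults`
- `protocolSection.armsInterventionsModule.armGroups.label`
- `protocolSection.armsInterventionsModule.interventions.name`
- `protocolSection.armsInterventionsModule.interventions.type`
- `protocolSection.contactsLocationsModule.locations.facility`
- `protocolSection.descriptionModule.briefSummary`
- `protocolSection.designModule.designInfo.allocation`
- `protocolSection.designModule.designInfo.interventionModel`
- `protocolSection.designModule.enrollmentInfo.count`
- `protocolSection.designModule.enrollmentInfo.type`
- `protocolSection.designModule.phases`
- `protocolSection.designModule.studyType`
- `protocolSection.eligibilityModule.maximumAge`
- `protocolSection.eligibilityModule.minimumAge`
- `protocolSection.identificationModule.briefTitle`
- `protocolSection.identificationModule.nctId`
- `protocolSection.identificationModule.secondaryIdInfos.id`
- `protocolSection.outcomesModule.primaryOutcomes.description`
- `protocolSection.outcomesModule.primaryOutcomes.measure`
- `protocolSection.outcomesModule.primaryOutcomes.timeFrame`
- `protocolSection.sponsorCollaboratorsModule.collaborators.class`
- `protocolSection.sponsorCollaboratorsModule.leadSponsor.class`
- `protocolSection.statusModule.completionDateStruct.date`
- `protocolSection.statusModule.lastKnownStatus`
- `protocolSection.statusModule.overallStatus`
- `protocolSection.statusModule.resultsFirstPostDateStruct.date`
- `protocolSection.statusModule.startDateStruct.date`
- `protocolSection.statusModule.startDateStruct.type`
- `protocolSection.statusModule.studyFirstSubmitDate`
- `protocolSection.statusModule.whyStopped`
- `resultsSection.outcomeMeasuresModule.outcomeMeasures.analyses.pValue`
- `resultsSection.outcomeMeasuresModule.outcomeMeasures.analyses.statisticalMethod`

### CTIS
- `ctNumber`
- `endDate`
- `endpoints.primary.description`
- `endpoints.primary.timeframe`
- `endpoints.primary.title`
- `interventions.name`
- `objectives`
- `overallStatus`
- `population.maximumAge`
- `population.minimumAge`
- `randomised`
- `recruitment.actualSubjects`
- `recruitment.plannedSubjects`
- `recruitmentStatus`
- `secondaryIdentifiers.id`
- `sites.name`
- `sponsors.type`
- `startDate.actualDate`
- `startDate.decisionDate`
- `startDate.plannedDate`
- `title`
- `trialPhase`

### EUCTR
- `endpoints.primary_endpoint.description`
- `endpoints.primary_endpoint.timeframe`
- `endpoints.primary_endpoint.title`
- `identification.ctis_number`
- `identification.eudract_number`
- `identification.isrctn_number`
- `identification.nct_number`
- `imp.product.name`
- `participating_countries.country.code`
- `participating_countries.country.eea`
- `population.age_groups.adults`
- `population.age_groups.children`
- `population.age_groups.elderly`
- `population.planned_subjects`
- `results.actual_enrollment`
- `results.end_of_trial_status`
- `results.primary_analysis.p_value`
- `results.primary_analysis.statistical_method`
- `results.publication_date`
- `sponsors.sponsor.status`
- `trial_dates.actual_start_date`
- `trial_dates.date_of_competent_authority_decision`
- `trial_dates.global_end_of_trial_date`
- `trial_dates.planned_start_date`
- `trial_information.full_title`
- `trial_information.main_objective`
- `trial_information.randomised`
- `trial_information.trial_phase.confirmatory`
- `trial_information.trial_phase.exploratory`
- `trial_information.trial_phase.human_pharmacology`
- `trial_information.trial_phase.therapeutic_use`
- `trial_status`

### ISRCTN
- `dateAssigned`
- `externalRefs.clinicalTrialsGovNumber`
- `externalRefs.ctisNumber`
- `externalRefs.eudraCTNumber`
- `interventions.intervention.drugNames`
- `interventions.intervention.interventionType`
- `isrctn`
- `outcomes.primaryOutcome.description`
- `outcomes.primaryOutcome.timepoints`
- `participants.lowerAgeLimit`
- `participants.targetEnrolment`
- `participants.totalCentres`
- `participants.totalFinalEnrolment`
- `participants.upperAgeLimit`
- `sponsors.sponsor.sponsorType`
- `trialDescription.studyHypothesis`
- `trialDescription.title`
- `trialDesign.overallEndDate`
- `trialDesign.overallStartDate`
- `trialDesign.overallStatus`
- `trialDesign.primaryStudyDesign`
- `trialDesign.recruitmentStatus`
- `trialDesign.studyDesign`
- `trialDesign.trialPhase`

## Value sets

Status, phase and sponsor-class literals per register are in
`vocabularies.yaml` (matched case-insensitively); EUCTR encodes phase as the
four yes/no flags above, CTGOV as an array of `PHASE*` tokens, CTIS/ISRCTN
as text literals. Secondary identifiers cross-reference co-registrations:
`secondaryIdInfos` (CTGOV), `secondaryIdentifiers` (CTIS),
`identification.{nct,ctis,isrctn}_number` (EUCTR), `externalRefs.*` (ISRCTN).
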