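# Default criterion catalogue for both prioritisation streams.
# Criteria are data, not code: local adaptations may edit this file (or supply
# their own) as long as each stream keeps one multiplier criterion and, unless
# count enforcement is relaxed, 3 (risk) / 4 (disease) weighted criteria.
# Rubric levels map in order to ordinal scores 1, 2, 3; for the two strategy
# criteria a HIGHER score means a WORSE situation (3 = no strategy available).
risk:
  - id: scope
    label: Scope of exposure
    role: weighted
    question: What proportion of the population is exposed to the particular risk factor?
    rubric:
      - Less than 20% of the population
      - 20-50% of the population
      - More than 50% of the population
  - id: frequency
    label: Frequency of exposure
    role: weighted
    question: What is the estimated frequency of the exposure?
    rubric:
      - Improbable
      - Occasional
      - Frequently
  - id: mitigation
    label: Mitigation strategy
    role: weighted
    question: Is any strategy available to mitigate the risk?
    rubric:
      - Strategy available (policy/norms/regulations or similar)
      - Strategy available (guidelines/communication material or similar)
      - No strategy
  - id: outbreak
    label: Potential for outbreak
    role: multiplier
    question: What is the potentiality of an outbreak of diseases in humans due to the concerned risk factor?
    rubric:
      - Low
      - Medium
      - High
disease:
  - id: severity
    label: Severity
    role: weighted
    question: What is the CFR in humans and animals?
    rubric:
      - CFR < 5% in one or both sectors
      - CFR >= 5% and < 15% in one or both sectors
      - CFR >= 15% in one or both sectors
  - id: prevalence
    label: Prevalence
    role: weighted
    question: What is the estimated prevalence of this disease?
    rubric:
      - Less than 1 per 100,000 population
      - 1-100 per 100,000 population
      - More than 100 per 100,000 population
  - id: transmissibility
    label: Transmissibility
    role: weighted
    question: Has this disease caused an epidemic (human or animal) in your region?
    rubric:
      - Never, or more than 10 years ago
      - Within the past 5 to 10 years
      - Within the past 5 years
  - id: strategy
    label: Preventive and control strategy
    role: weighted
    question: Is a strategy for disease prevention and control readily available?
    rubric:
      - Available for animals and humans
      - Available for animals or humans
      - Not available for animals and humans
  - id: burden
    label: Disease burden
    role: multiplier
    question: Is the disease a burden among humans and animals?
    rubric:
      - Neither
      - High DALY among humans, or high economic/animal loss
      - High DALY among humans and high economic/animal loss
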