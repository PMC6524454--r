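{
  "neg_cues": ["No", "No evidence of", "There is no", "There is no evidence of",
               "Without evidence of", "No definite", "Negative for"],
  "neg_findings": ["acute infarct", "acute infarction", "acute or subacute infarct",
                   "acute ischemic infarct", "recent infarct", "acute infarcts"],
  "neg_tails": ["", "is seen", "is identified", "on this examination",
                "on today's study", "in either hemisphere"],
  "neg_templates_site_b": [
    "No acute infarct.",
    "No acute infarction.",
    "No acute intracranial infarct.",
    "No evidence of acute infarction.",
    "No acute ischemic infarct.",
    "No acute infarct is identified.",
    "No acute infarct is seen.",
    "There is no acute infarction.",
    "No evidence of acute infarct.",
    "No acute or subacute infarct.",
    "Negative for acute infarction.",
    "No recent infarct."
  ],
  "chronic_modifiers": ["Chronic", "Old", "Remote", "Stable"],
  "sbi_findings": ["infarct", "infarction", "lacune", "lacunar infarct"],
  "anatomy": ["left basal ganglia", "right basal ganglia", "left thalamus",
              "right thalamus", "left corona radiata", "right corona radiata",
              "left centrum semiovale", "right cerebellar hemisphere",
              "left caudate nucleus", "pons"],
  "sbi_positive_frames": [
    "{mod} {find} in the {anat}.",
    "There is a {modl} {find} in the {anat}.",
    "{mod} {find} involving the {anat}.",
    "Encephalomalacia with {modl} {find} in the {anat}."
  ],
  "sbi_hedged_frames": [
    "Probable {modl} {find} in the {anat}.",
    "Possible {modl} {find} in the {anat}.",
    "Findings likely represent {modl} {find} in the {anat}."
  ],
  "coref_pairs": [
    ["There is a focal area of encephalomalacia and gliosis in the {anat}.",
     "The above findings are nonspecific but likely reflect remote ischemic insult."],
    ["Area of cystic encephalomalacia with surrounding gliosis in the {anat}.",
     "The findings described above are compatible with old ischemic injury."]
  ],
  "historical_templates": [
    "History of remote infarction on prior imaging.",
    "Known old lacune in the {anat}, unchanged.",
    "History of prior lacunar infarction, stable.",
    "Previously seen remote infarct in the {anat}, stable in appearance."
  ],
  "confounder_anatomy": ["right occipital lobe", "right parietal lobe",
                         "right subinsular region", "left frontal region",
                         "left frontal lobe", "right cerebellar hemisphere"],
  "confounder_frames": [
    "Scattered foci of susceptibility artifact in the {a1}, {a2} and {a3}.",
    "Bilateral intraparenchymal foci of susceptibility artifact in the {a1} and {a2}.",
    "Punctate focus of mineralization in the {a1}.",
    "Foci of T2 prolongation in the {a1}, {a2} and {a3}."
  ],
  "wmd_severity": ["Mild", "Moderate", "Severe", "Extensive"],
  "wmd_findings": ["white matter microvascular ischemic", "microvascular ischemic",
                   "periventricular white matter"],
  "wmd_positive_frames": [
    "{sev} chronic {wfind} changes.",
    "{sev} {wfind} disease.",
    "{sev} confluent {wfind} signal abnormality.",
    "Scattered foci of {wfind} change in a pattern typical for age.",
    "{sev} leukoaraiosis."
  ],
  "wmd_hedged_frames": [
    "Probable {sevl} {wfind} changes.",
    "Possibly {sevl} {wfind} change."
  ],
  "wmd_negative_templates": [
    "No significant white matter signal abnormality.",
    "No white matter signal abnormality.",
    "No evidence of white matter disease.",
    "No significant white matter hyperintensities.",
    "Multilevel degenerative changes of the visualized cervical spine.",
    "Mild white matter degenerative changes."
  ],
  "fillers": [
    "The ventricles and sulci are within normal limits for age.",
    "No mass effect or midline shift.",
    "The major intracranial flow voids are preserved.",
    "No extra-axial fluid collection.",
    "Gray-white differentiation is preserved."
  ],
  "indications": ["Headache", "Dizziness", "Gait instability",
                  "Visual disturbance", "Syncope", "Vertigo"]
}
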