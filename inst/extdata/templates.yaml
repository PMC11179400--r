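op_normal: operative report, {eye} eye. an anterior chamber paracentesis was performed
  at the start of the case and 50 to 100 microliters of aqueous humor was aspirated
  using a 30-gauge {instrument}. the anterior chamber remained deep and formed throughout.
  there was no lens touch, no iris touch, and no cornea touch. no bleeding, no hyphema,
  and no suprachoroidal hemorrhage were observed. the wound was watertight without
  leak. no descemet membrane tear was noted. the patient tolerated the procedure well
  without movement.
op_complication: operative report, {eye} eye. an anterior chamber paracentesis was
  performed at the start of the case and 50 to 100 microliters of aqueous humor was
  aspirated using a 30-gauge {instrument}. on withdrawal of aqueous there was shallowing
  of the anterior chamber, which was reinflated with balanced salt solution, at which
  time a small descemet membrane tear was noted adjacent to the paracentesis. the
  tear remained localized and small without extension. there was no lens touch, no
  iris touch, and no cornea touch. no bleeding, no hyphema, and no suprachoroidal
  hemorrhage were observed. the wound was watertight without leak. the patient tolerated
  the procedure well without movement.
op_endo_indication_prefix: 'indication: endophthalmitis, {eye} eye. pars plana vitrectomy
  with intravitreal antibiotics was performed.'
adversarial_sentence: the tear film was stable and the wound was leak-free at the
  conclusion of the case.
note_followup: postoperative day {day} visit, {eye} eye. the eye is quiet and the
  vision is stable. cornea clear, anterior chamber deep and formed, no hyphema. the
  wound is seidel negative without leak. no signs of endophthalmitis.
note_preexisting_endo: patient seen in clinic for acute endophthalmitis of the {eye}
  eye. intravitreal antibiotics were administered and the infection is improving.
anesthesia_topical_a: topical anesthesia with intracameral lidocaine was administered.
anesthesia_topical_b: topical tetracaine drops were applied at the start of the case.
anesthesia_misuse: transient general anesthesia with intravenous sedation; topical
  drops were applied.
anesthesia_peribulbar: peribulbar block with 2% lidocaine and 0.75% bupivacaine.
anesthesia_subtenon: subtenon anesthesia with lidocaine was administered.
anesthesia_retrobulbar: retrobulbar block with lidocaine under monitored anesthesia
  care.
anesthesia_general: general endotracheal anesthesia.
anesthesia_no_hit_text: monitored anesthesia care.
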