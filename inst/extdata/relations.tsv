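id	transitive	reflexive	priority_over_subsumption	superrelations	compositions
is_a	true	false	false		
part_of	true	false	false		part_of>part_of
participates_in	false	false	true		
has_function	false	false	true		
located_in	false	false	true		
member_of_pathway	false	false	false		
encoded_by	false	false	false		
has_modified_residue	false	false	false		
in_taxon	false	false	false		
has_participant	false	false	false		
has_interaction_type	false	false	false		
regulates	false	false	false		
activates	false	false	false	regulates	
represses	false	false	false	regulates	
directly_participates_in	false	false	false	participates_in	
directly_has_function	false	false	false	has_function	
directly_located_in	false	false	false	located_in	
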