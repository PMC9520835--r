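# Miniature Biolink-style semantic model used by the synthetic source suite
# and the package examples: category and predicate hierarchies, inverse
# predicate pairs (one canonical member each), symmetric predicates, the
# relation map for the suite's sources, and per-category identifier-prefix
# priorities for canonical-identifier election.
version: mini-1.0
categories:
  biolink:NamedThing:
    - biolink:BiologicalEntity
    - biolink:ChemicalEntity
    - biolink:InformationContentEntity
  biolink:BiologicalEntity:
    - biolink:DiseaseOrPhenotypicFeature
    - biolink:Gene
    - biolink:Protein
  biolink:DiseaseOrPhenotypicFeature:
    - biolink:Disease
    - biolink:PhenotypicFeature
  biolink:ChemicalEntity:
    - biolink:SmallMolecule
    - biolink:Drug
predicates:
  biolink:related_to:
    - biolink:interacts_with
    - biolink:treats
    - biolink:treated_by
    - biolink:subclass_of
    - biolink:superclass_of
    - biolink:same_as
    - biolink:associated_with
    - biolink:has_part
    - biolink:part_of
    - biolink:affects
  biolink:interacts_with:
    - biolink:physically_interacts_with
  biolink:same_as:
    - biolink:exact_match
inverse_pairs:
  - pair: [biolink:treats, biolink:treated_by]
    canonical: biolink:treats
  - pair: [biolink:subclass_of, biolink:superclass_of]
    canonical: biolink:subclass_of
  - pair: [biolink:has_part, biolink:part_of]
    canonical: biolink:has_part
symmetric:
  - biolink:interacts_with
  - biolink:physically_interacts_with
  - biolink:same_as
  - biolink:exact_match
relation_map:
  - {source: semtriples, relation: xref_to, predicate: biolink:same_as}
  - {source: semtriples, relation: treats_condition, predicate: biolink:treats}
  - {source: semtriples, relation: condition_treated_by, predicate: biolink:treated_by}
  - {source: semtriples, relation: gene_associated_with, predicate: biolink:associated_with}
  - {source: drugrecs, relation: treats, predicate: biolink:treats}
  - {source: drugrecs, relation: targets, predicate: biolink:affects}
  - {source: fixtureDrugDB, relation: treats_condition, predicate: biolink:treats}
prefix_priority:
  biolink:Disease: [MONDO, DOID, EFO, MESH]
  biolink:DiseaseOrPhenotypicFeature: [MONDO, DOID, EFO, MESH]
  biolink:Drug: [DRUGBANK, CHEBI, CHEMBL.COMPOUND, UMLS]
  biolink:ChemicalEntity: [CHEBI, DRUGBANK, CHEMBL.COMPOUND]
  biolink:Gene: [NCBIGene, UniProtKB]
  biolink:Protein: [UniProtKB, NCBIGene]
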