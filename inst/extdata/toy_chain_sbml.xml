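<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy_chain">
    <listOfSpecies>
      <species id="c1" compartment="cy" boundaryCondition="true"/>
      <species id="c2" compartment="cy" boundaryCondition="true"/>
      <species id="c3" compartment="cy"/>
      <species id="c4" compartment="cy"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r1" reversible="false">
        <listOfReactants>
          <speciesReference species="c1" stoichiometry="1"/>
          <speciesReference species="c2" stoichiometry="2"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="c3" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="r2" reversible="false">
        <listOfReactants>
          <speciesReference species="c3" stoichiometry="3"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="c4" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
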