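<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="M1">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_c" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="but_c" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="glc_e" compartment="e" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="but_e" compartment="e" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_big" value="1000" constant="true"/>
      <parameter id="lb_big" value="-1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="t_glc" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="glc_e" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="glc_c" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="r_but" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="glc_c" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="but_c" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="t_but" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="but_c" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="but_e" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="bm" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="glc_c" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="EX_glc" reversible="true" fast="false" fbc:lowerFluxBound="lb_big" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="glc_e" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="EX_but" reversible="true" fast="false" fbc:lowerFluxBound="lb_big" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="but_e" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="bm" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
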