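<Lems>
  <!-- Closed <-> open kinetic scheme with constant rates alpha (forward)
       and beta (reverse); steady-state open occupancy alpha/(alpha+beta)
       = 0.2. Occupancies are mean-field ODEs with conservation. -->
  <Include file="lems_core_types.xml"/>
  <Target component="sim1"/>

  <gateKS id="gate1">
    <kineticState id="c"/>
    <kineticState id="o"/>
    <constRateTransition id="t1" from="c" to="o" alpha="100 per_s"
                         beta="400 per_s"/>
  </gateKS>

  <Simulation id="sim1" length="50 ms" step="0.01 ms" target="gate1">
    <OutputFile id="of1" fileName="two_state_kinetic_gate.dat">
      <OutputColumn id="open" quantity="o/occupancy"/>
      <OutputColumn id="closed" quantity="c/occupancy"/>
    </OutputFile>
  </Simulation>
</Lems>
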