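<Lems>
  <!-- Linear test system dx/dt = -x/tau with known solution
       x(t) = x0 exp(-t/tau); used for integrator convergence checks. -->
  <Include file="lems_core_types.xml"/>
  <Target component="sim1"/>

  <ComponentType name="decayModel">
    <Parameter name="tau" dimension="time"/>
    <Parameter name="x0" dimension="none"/>
    <Exposure name="x" dimension="none"/>
    <Dynamics>
      <StateVariable name="x" dimension="none" exposure="x"/>
      <TimeDerivative variable="x" value="-x / tau"/>
      <OnStart>
        <StateAssignment variable="x" value="x0"/>
      </OnStart>
    </Dynamics>
  </ComponentType>

  <decayModel id="decay1" tau="1 s" x0="1"/>

  <Simulation id="sim1" length="1 s" step="0.1 s" target="decay1">
    <OutputFile id="of1" fileName="exp_decay.dat">
      <OutputColumn id="x" quantity="x"/>
    </OutputFile>
  </Simulation>
</Lems>
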