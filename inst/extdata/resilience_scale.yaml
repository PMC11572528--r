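- id: x1
  text: Professional quality
  weight: 0.346
  children:
  - id: x11
    text: Communication skills
    weight: 0.465
    children:
    - id: x111
      text: 'I can communicate well with the residents in dialect (for example in
        Guangdong province: Cantonese).'
      weight: 0.2
    - id: x112
      text: I can assist the unit in the documentation and publicity work (such as
        the writing of the official account of the unit, propaganda and education
        documents, etc.).
      weight: 0.396
    - id: x113
      text: At work, I can express academic ideas accurately, scientifically and rigorously,
        and exchange research results.
      weight: 0.404
  - id: x12
    text: Social mobilization
    weight: 0.035
    children:
    - id: x121
      text: I am willing to have the initiative to understand the public health situation
        at the global, national, regional and community levels.
      weight: 0.286
    - id: x122
      text: I would like to find community partners to carry out actions to promote
        the health of the residents.
      weight: 0.377
    - id: x123
      text: I will pay close attention to current public health policies and seek
        opportunities to participate in activities that improve them.
      weight: 0.337
  - id: x13
    text: Teamwork
    weight: 0.185
    children:
    - id: x131
      text: When performing tasks, I prefer team tasks where I can work with others.
      weight: 0.275
    - id: x132
      text: When carrying out emergency rescue tasks with the team, I will actively
        learn task-related information and actively share with members.
      weight: 0.725
  - id: x14
    text: Organization and coordination skills
    weight: 0.315
    children:
    - id: x141
      text: During public health operations, I can quickly adjust myself to align
        my work status with the organization's activities.
      weight: 0.512
    - id: x142
      text: I can encourage others to participate in action so as to promote internal
        collaboration.
      weight: 0.488
- id: x2
  text: Psychological capital
  weight: 0.614
  children:
  - id: x21
    text: Optimism
    weight: 0.039
    children:
    - id: x211
      text: I always see the bright side of things in my work.
      weight: 0.275
    - id: x212
      text: I am optimistic about what will happen to my job in the future.
      weight: 0.259
    - id: x213
      text: In the face of public health events such as the COVID-19 pandemic, I always
        believe that there is a light at the end of the tunnel, do not be pessimistic.
      weight: 0.466
  - id: x22
    text: Toughness
    weight: 0.198
    children:
    - id: x221
      text: I believe I can work through any challenge I have at work.
      weight: 0.22
    - id: x222
      text: I can do it on my own if I have to do hard work alone.
      weight: 0.254
    - id: x223
      text: I usually take stress at work in stride.
      weight: 0.063
    - id: x224
      text: Even in the face of public health outbreaks, I am able to survive difficult
        times at work.
      weight: 0.23
    - id: x225
      text: In my current job, I feel like I can juggle many things at once.
      weight: 0.234
  - id: x23
    text: Hope
    weight: 0.318
    children:
    - id: x231
      text: If I find myself stuck at work, I can think of many ways to get out of
        it.
      weight: 0.313
    - id: x232
      text: At present, I am full of energy to complete my work goals.
      weight: 0.097
    - id: x233
      text: There are many solutions to any problem.
      weight: 0.137
    - id: x234
      text: At the moment I am quite satisfied with what I have achieved in my work.
      weight: 0.1
    - id: x235
      text: I can think of a number of ways to achieve my current workday goals.
      weight: 0.192
    - id: x236
      text: At the moment, I am achieving the work goals I set for myself.
      weight: 0.161
  - id: x24
    text: Effectiveness
    weight: 0.445
    children:
    - id: x241
      text: I believe I can analyze long-term problems and find solutions.
      weight: 0.163
    - id: x242
      text: In meetings, I am confident in stating things that are within the scope
        of my job.
      weight: 0.065
    - id: x243
      text: I think I can improve the general well-being in the community which I
        work for.
      weight: 0.184
    - id: x244
      text: Within the scope of my job, I believe I can help set goals/objectives.
      weight: 0.137
    - id: x245
      text: I believe in my ability to connect with people outside my working department
        to solve some related problems.
      weight: 0.177
    - id: x246
      text: If I were in the scene of a public health emergency, I believe I would
        be able to calmly analyze the situation and work on the front lines as soon
        as possible.
      weight: 0.273
- id: x3
  text: Emergency attitude
  weight: 0.04
  children:
  - id: x31
    text: Disaster relief expectation
    weight: 0.277
    children:
    - id: x311
      text: If I have chance, I am willing to participate in the rescue work of public
        health emergencies.
      weight: 0.277
    - id: x312
      text: If I have chance, I am willing to assist in the disinfection of the epidemic
        area.
      weight: 0.218
    - id: x313
      text: During the public health emergency, I would be willing to receive psychological
        training to provide the psychological care and interventions that patients
        or community residents need.
      weight: 0.235
    - id: x314
      text: As a grass-roots medical worker, if I realize that there is a crisis of
        public health events such as infectious diseases, I will do all in my power
        to send a protective warning to the outside world.
      weight: 0.269
  - id: x32
    text: Trained attitude
    weight: 0.191
    children:
    - id: x321
      text: I am willing to learn more about public health emergencies.
      weight: 0.197
    - id: x322
      text: It is necessary to carry out public health emergency related courses and
        training.
      weight: 0.259
    - id: x323
      text: It is necessary to carry out emergency drills for public health emergencies.
      weight: 0.246
    - id: x324
      text: It is important to master the basic knowledge of public health emergencies.
      weight: 0.297
  - id: x33
    text: Mental reaction
    weight: 0.04
    children:
    - id: x331
      text: I am terrified of a public health emergency.
      weight: 0.533
    - id: x332
      text: Performing tasks related to public health emergencies such as daily epidemic
        prevention will make me feel stressed.
      weight: 0.467
  - id: x34
    text: Awareness of prevention
    weight: 0.363
    children:
    - id: x341
      text: It is necessary to equip the household with emergency medicine kit (containing
        disinfectant, mask, anti-inflammatory drugs, anti-allergic drugs and other
        items), fire extinguisher and other basic emergency materials.
      weight: 0.256
    - id: x342
      text: I am willing to assist community residents to carry out preventive vaccination
        and preventive medication.
      weight: 0.336
    - id: x343
      text: I am willing to actively communicate with community residents and carry
        out health education on public health emergencies.
      weight: 0.409
  - id: x35
    text: Self-evaluation
    weight: 0.129
    children:
    - id: x351
      text: I am familiar with public health emergencies.
      weight: 0.356
    - id: x352
      text: I will pay attention to the epidemic situation of local infectious diseases
        actively.
      weight: 0.299
    - id: x353
      text: I will follow the World Health Organization's reports on various public
        health emergencies.
      weight: 0.345
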